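# Duplex thermodynamics: nearest-neighbor summation, van't Hoff constants,
# two-state melting model and Tm.

test_that("nearest-neighbor prediction equals the explicit per-step summation", {
  tab <- read_nn_table()
  # single-step 2-mer: one stack plus two initiation terms
  th2 <- nn_duplex_thermo("AC", revcomp("AC"), tab)
  expect_equal(th2$dH,
               tab$dH_kcal[tab$step == "AC"] + tab$dH_kcal[tab$step == "init_AT"] +
                 tab$dH_kcal[tab$step == "init_GC"])
  # 10-mer against the independent hand-summation oracle
  probe <- "GATCCGTAGC"
  th <- nn_duplex_thermo(probe, revcomp(probe), tab)
  oracle <- oracle_nn_sum(probe, nn_table_path())
  expect_equal(th$dH, unname(oracle["dH"]), tolerance = 1e-12)
  expect_equal(th$dS, unname(oracle["dS"]), tolerance = 1e-12)
  expect_identical(th$source, "nearest_neighbor")
  # probe binding an interior window of a longer template
  th_win <- nn_duplex_thermo(probe, paste0("TTT", revcomp(probe), "GGG"), tab)
  expect_equal(th_win$dH, th$dH)
})

test_that("nearest-neighbor additivity holds across concatenation", {
  tab <- read_nn_table()
  s1 <- "ACGTA"; s2 <- "AGGCT"   # s2 starts with s1's last base -> shared stack
  whole <- paste0(s1, substr(s2, 2, nchar(s2)))
  th_whole <- nn_duplex_thermo(whole, revcomp(whole), tab)
  o1 <- oracle_nn_sum(s1, nn_table_path())
  o2 <- oracle_nn_sum(s2, nn_table_path())
  # steps add; subtract the doubly counted initiation at the junction ends
  junction <- substr(s1, nchar(s1), nchar(s1))
  init <- if (junction %in% c("A", "T")) "init_AT" else "init_GC"
  tabH <- read.table(nn_table_path(), header = TRUE)
  expect_equal(th_whole$dH,
               unname(o1["dH"] + o2["dH"]) - 2 * tabH$dH_kcal[tabH$step == init],
               tolerance = 1e-12)
})

test_that("complementarity and alphabet violations are reported with position", {
  expect_error(nn_duplex_thermo("ACGT", "ACGA"), "position")
  expect_error(nn_duplex_thermo("ACNT", revcomp("ACGT")), "base 'N' at position 3")
  expect_error(nn_duplex_thermo("A", "T"), "at least 2")
})

test_that("van't Hoff K is positive, correct at dG = 0, and monotone decreasing", {
  # dG(T) = 0 => K = 1: pick dS so dH - T dS = 0 at 298.15 K
  dH <- -50; T0 <- 298.15
  th0 <- suppressWarnings(duplex_thermo(dH, dH / T0 * 1000))
  expect_equal(vant_hoff_K(th0, T0), 1, tolerance = 1e-12)
  th <- duplex_thermo(-70, -190)
  temps <- seq(273.15, 373.15, by = 5)
  K <- vant_hoff_K(th, temps)
  expect_true(all(K > 0))
  expect_true(all(diff(K) < 0))
  expect_error(vant_hoff_K(th, -10), "positive")
  expect_error(vant_hoff_K(th, NaN), "finite")
})

test_that("dG = -13.57 kcal/mol at 25 C gives K near 8.82e9 1/M", {
  # direct evaluation of exp(-dG/RT); dS chosen so dG(298.15) = -13.57
  dG <- -13.57; T0 <- 298.15; dH <- -70
  th <- duplex_thermo(dH, (dH - dG) / T0 * 1000)
  K <- vant_hoff_K(th, T0)
  expect_equal(K, exp(-dG / (1.9872e-3 * T0)), tolerance = 1e-12)
  expect_equal(K, 8.82e9, tolerance = 0.005)
})

test_that("ln K is affine in 1/T", {
  th <- duplex_thermo(-65, -175)
  temps <- c(290, 310, 330)
  lnK <- log(vant_hoff_K(th, temps))
  x <- 1 / temps
  slope12 <- (lnK[2] - lnK[1]) / (x[2] - x[1])
  slope23 <- (lnK[3] - lnK[2]) / (x[3] - x[2])
  expect_equal(slope12, slope23, tolerance = 1e-12)
  expect_equal(slope12, 65 / 1.9872e-3, tolerance = 1e-12)
})

test_that("two-state theta and Tm are mutually consistent", {
  th <- duplex_thermo(-70, -190)
  C <- 4e-6
  tm <- melting_temperature(th, C)
  expect_equal(theta_two_state(th, tm, C), 0.5, tolerance = 1e-9)
  # raising the concentration raises Tm
  expect_gt(melting_temperature(th, 4e-5), tm)
  # no root in range
  expect_error(melting_temperature(duplex_thermo(-200, -450), 4e-6), "120")
})

test_that("noiseless melt fit recovers (dH, dS) and Tm round-trips", {
  th <- duplex_thermo(-70, -190)
  curve <- gen_melting_curve(th, 4e-6, seq(10, 90, by = 2), noise_spec(sd = 0))
  fit <- fit_two_state_melt(curve)
  expect_equal(fit$dH, -70, tolerance = 1e-3)   # 0.1% relative
  expect_equal(fit$dS, -190, tolerance = 1e-3)
  expect_equal(melting_temperature(fit, 4e-6), melting_temperature(th, 4e-6),
               tolerance = 0.1 / 50)  # 0.1 C on a ~50 C Tm
  # generate -> fit -> K reproduces the generating K
  expect_equal(vant_hoff_K(fit, 298.15), vant_hoff_K(th, 298.15), tolerance = 1e-3)
  expect_s3_class(fit, "melt_fit")
  expect_lt(fit$residual_norm, 1e-8)
})

test_that("degenerate melting curves are rejected as non-identifiable", {
  curve_flat <- melting_curve(seq(10, 60, 10), rep(1, 6), 4e-6)
  expect_error(fit_two_state_melt(curve_flat), "identifiab")
  curve_melted <- melting_curve(seq(10, 60, 10), rep(0.001, 6), 4e-6)
  expect_error(fit_two_state_melt(curve_melted), "identifiab")
  expect_error(fit_two_state_melt(melting_curve(seq(10, 40, 10), c(1, .8, .5, .2), 4e-6)),
               "6 points")
})

test_that("melt fit tolerates measurement noise in the study regime", {
  set.seed(2024)
  truth <- duplex_thermo(-70, -190)
  K_true <- vant_hoff_K(truth, 298.15)
  errs <- replicate(100, {
    mc <- gen_melting_curve(truth, 4e-6, seq(10, 90, by = 2), noise_spec(sd = 0.01))
    (vant_hoff_K(fit_two_state_melt(mc), 298.15) - K_true) / K_true
  })
  expect_lt(median(abs(errs)), 0.25)
  expect_lt(abs(median(errs)), 0.10)
})

test_that("NN table validation catches malformed tables", {
  tmp <- tempfile(fileext = ".tsv")
  tab <- read.table(nn_table_path(), header = TRUE)
  write.table(tab[tab$step != "AA", ], tmp, row.names = FALSE, sep = "\t", quote = FALSE)
  expect_error(read_nn_table(tmp), "missing steps")
  tab2 <- tab; tab2$dH_kcal[tab2$step == "GC"] <- 1
  write.table(tab2, tmp, row.names = FALSE, sep = "\t", quote = FALSE)
  expect_error(read_nn_table(tmp), "negative")
})
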