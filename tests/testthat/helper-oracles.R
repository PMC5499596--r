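# Independent oracles used to cross-check the implementation by a different
# computational route.

# Speciation oracle: scan free template on a grid with a damped fixed-point
# inner solve for the free probe strands (the implementation instead uses
# closed-form quadratic elimination + pure bisection), then refine the
# bracket by bisection.
oracle_free_ab <- function(t, K_A, K_B, omega, At, Bt) {
  a <- rep(At, length(t)); b <- rep(Bt, length(t))
  for (i in 1:4000) {
    a_new <- At / (1 + K_A * t + omega * K_A * K_B * t * b)
    b_new <- Bt / (1 + K_B * t + omega * K_A * K_B * t * a_new)
    step <- max(abs(a_new - a) / pmax(a_new, 1e-300),
                abs(b_new - b) / pmax(b_new, 1e-300))
    a <- (a + a_new) / 2; b <- (b + b_new) / 2
    if (step < 1e-15) break
  }
  list(a = a, b = b)
}

oracle_speciation <- function(K_A, K_B, omega, Tt, At, Bt, n_grid = 2000) {
  g_of <- function(t, ab) {
    t * (1 + K_A * ab$a + K_B * ab$b + omega * K_A * K_B * ab$a * ab$b) - Tt
  }
  grid <- seq(0, Tt, length.out = n_grid)
  gv <- g_of(grid, oracle_free_ab(grid, K_A, K_B, omega, At, Bt))
  i <- max(which(gv <= 0))
  lo <- grid[i]; hi <- if (i < n_grid) grid[i + 1] else Tt
  for (iter in 1:200) {
    mid <- (lo + hi) / 2
    if (g_of(mid, oracle_free_ab(mid, K_A, K_B, omega, At, Bt)) > 0) hi <- mid else lo <- mid
    if ((hi - lo) <= 1e-18 * Tt) break
  }
  t <- (lo + hi) / 2
  ab <- oracle_free_ab(t, K_A, K_B, omega, At, Bt)
  TAB <- omega * K_A * K_B * t * ab$a * ab$b
  list(free_template = t, free_a = ab$a, free_b = ab$b, TAB = TAB)
}

# Explicit per-step nearest-neighbor summation, written as a plain loop over
# the probe, independent of the package's vectorized lookup.
oracle_nn_sum <- function(probe_seq, table_path) {
  tab <- read.table(table_path, header = TRUE, stringsAsFactors = FALSE)
  get <- function(step, col) tab[tab$step == step, col]
  dH <- 0; dS <- 0
  for (i in seq_len(nchar(probe_seq) - 1)) {
    st <- substr(probe_seq, i, i + 1)
    dH <- dH + get(st, "dH_kcal"); dS <- dS + get(st, "dS_cal")
  }
  for (end in c(substr(probe_seq, 1, 1), substr(probe_seq, nchar(probe_seq), nchar(probe_seq)))) {
    init <- if (end %in% c("A", "T")) "init_AT" else "init_GC"
    dH <- dH + get(init, "dH_kcal"); dS <- dS + get(init, "dS_cal")
  }
  c(dH = dH, dS = dS)
}

nn_table_path <- function() system.file("extdata", "nn_unified_dna.tsv", package = "eptlig")

# Remaining-acceptor fraction by numerical quadrature of the decaying rate,
# independent of the analytic antiderivative used in closed_form_competing.
oracle_quadrature_remaining <- function(k0, k_hyd, t) {
  vapply(t, function(ti) {
    if (ti == 0) return(1)
    I <- stats::integrate(function(s) exp(-k_hyd * s), 0, ti,
                          rel.tol = 1e-12, abs.tol = 1e-14)$value
    exp(-k0 * I)
  }, numeric(1))
}
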