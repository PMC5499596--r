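# Duplex formation thermodynamics: nearest-neighbor prediction, van't Hoff
# equilibrium constants, the two-state melting model and Tm.
#
# Conventions (applied consistently across the package):
#   * dH in kcal/mol, dS in cal/(mol*K); both negative for a forming duplex.
#   * R = 1.9872e-3 kcal/(mol*K); temperatures stored in kelvin internally,
#     exposed in degrees Celsius.
#   * Non-self-complementary duplex with equal strand totals C per strand;
#     theta is the fraction of the limiting strand in duplex, so
#     K = theta / ((1 - theta)^2 * C) and K(Tm) * C = 2 at theta = 1/2.

#' Duplex formation thermodynamics
#'
#' Container for the enthalpy and entropy of duplex formation, from which
#' the association constant K(T) and melting temperature derive.
#'
#' @param dH enthalpy of duplex formation, kcal/mol (negative for a forming duplex).
#' @param dS entropy of duplex formation, cal/(mol*K) (negative likewise).
#' @param source provenance: "nearest_neighbor", "melt_fit" or "user_supplied".
#' @return an object of class \code{"duplex_thermo"}.
#' @export
duplex_thermo <- function(dH, dS, source = c("user_supplied", "nearest_neighbor", "melt_fit")) {
  source <- match.arg(source)
  stopifnot_finite(dH, "dH"); stopifnot_finite(dS, "dS")
  if (dH >= 0 || dS >= 0) {
    warning("a forming duplex normally has dH < 0 and dS < 0", call. = FALSE)
  }
  structure(list(dH = dH, dS = dS, source = source), class = "duplex_thermo")
}

#' @export
print.duplex_thermo <- function(x, ...) {
  cat(sprintf("Duplex thermodynamics (%s)\n", x$source))
  cat(sprintf("  dH = %.2f kcal/mol, dS = %.1f cal/(mol K)\n", x$dH, x$dS))
  cat(sprintf("  K(25 C) = %.3g 1/M\n", vant_hoff_K(x, 25 + C_TO_K)))
  invisible(x)
}

#' Read a nearest-neighbor parameter table
#'
#' Tab- or comma-delimited text with header \code{step, dH_kcal, dS_cal};
#' dinucleotide steps are keyed by the probe-strand dinucleotide read 5'->3',
#' and the rows \code{init_AT} / \code{init_GC} hold the duplex initiation
#' terms for a terminal A.T or G.C pair.
#'
#' @param path file path; default is the unified DNA/DNA table shipped with
#'   the package.
#' @return a data frame of class \code{"nn_table"}.
#' @export
read_nn_table <- function(path = system.file("extdata", "nn_unified_dna.tsv", package = "eptlig")) {
  tab <- utils::read.delim(path, sep = "", stringsAsFactors = FALSE)
  need <- c("step", "dH_kcal", "dS_cal")
  if (!all(need %in% names(tab))) {
    stop(sprintf("NN table '%s' must have columns %s", path, paste(need, collapse = ", ")),
         call. = FALSE)
  }
  steps <- expand.grid(a = c("A", "C", "G", "T"), b = c("A", "C", "G", "T"))
  canonical <- paste0(steps$a, steps$b)
  present <- tab$step[tab$step %in% canonical]
  if (anyDuplicated(present)) stop("duplicate dinucleotide step in NN table", call. = FALSE)
  if (!all(canonical %in% present)) {
    stop(sprintf("NN table missing steps: %s",
                 paste(setdiff(canonical, present), collapse = ", ")), call. = FALSE)
  }
  if (any(tab$dH_kcal[tab$step %in% canonical] >= 0)) {
    stop("all dinucleotide step enthalpies must be negative", call. = FALSE)
  }
  if (!all(c("init_AT", "init_GC") %in% tab$step)) {
    stop("NN table must include init_AT and init_GC rows", call. = FALSE)
  }
  class(tab) <- c("nn_table", "data.frame")
  tab
}

nn_lookup <- function(tab, step) {
  i <- match(step, tab$step)
  if (any(is.na(i))) stop(sprintf("step '%s' not in NN table", step[which(is.na(i))[1]]), call. = FALSE)
  list(dH = tab$dH_kcal[i], dS = tab$dS_cal[i])
}

#' Nearest-neighbor duplex thermodynamics
#'
#' Predicts (dH, dS) for a probe hybridized to a perfectly complementary
#' contiguous window of a template, as the sum of stacked dinucleotide step
#' terms along the probe plus the two terminal initiation terms.
#'
#' @param probe,template \code{\link{strand}} objects or plain sequences
#'   (5'->3', DNA alphabet).
#' @param params an \code{nn_table} from \code{\link{read_nn_table}}.
#' @param dS_correction additive entropy correction, cal/(mol*K); hook for a
#'   user-supplied salt adjustment (default 0, no correction).
#' @return a \code{\link{duplex_thermo}} with source \code{"nearest_neighbor"}.
#' @export
nn_duplex_thermo <- function(probe, template, params = read_nn_table(), dS_correction = 0) {
  pseq <- if (inherits(probe, "ept_strand")) probe$sequence else toupper(probe)
  tseq <- if (inherits(template, "ept_strand")) template$sequence else toupper(template)
  check_alphabet(pseq, "DNA"); check_alphabet(tseq, "DNA")
  n <- nchar(pseq)
  if (n < 2) stop("probe must be at least 2 nt", call. = FALSE)
  if (n > nchar(tseq)) stop("probe longer than template", call. = FALSE)
  target <- revcomp(pseq, "DNA")
  # locate the best window of the template; demand perfect complementarity
  tch <- strsplit(tseq, "")[[1]]
  wch <- strsplit(target, "")[[1]]
  best <- NULL; best_matches <- -1L
  for (s in seq_len(nchar(tseq) - n + 1)) {
    m <- sum(tch[s:(s + n - 1)] == wch)
    if (m > best_matches) { best_matches <- m; best <- s }
  }
  if (best_matches < n) {
    mism <- which(tch[best:(best + n - 1)] != wch)[1]
    # report in probe coordinates (probe position pairing template position)
    stop(sprintf("probe is not complementary to template: mismatch at probe position %d",
                 n - mism + 1), call. = FALSE)
  }
  pch <- strsplit(pseq, "")[[1]]
  steps <- paste0(pch[-n], pch[-1])
  vals <- nn_lookup(params, steps)
  ends <- pch[c(1, n)]
  init_steps <- ifelse(ends %in% c("A", "T"), "init_AT", "init_GC")
  inits <- nn_lookup(params, init_steps)
  duplex_thermo(dH = sum(vals$dH) + sum(inits$dH),
                dS = sum(vals$dS) + sum(inits$dS) + dS_correction,
                source = "nearest_neighbor")
}

#' Van't Hoff association constant
#'
#' K(T) = exp(-(dH - T dS) / (R T)) with dH in kcal/mol, dS in cal/(mol*K)
#' and R = 1.9872e-3 kcal/(mol*K). Strictly positive and, for a forming
#' duplex (dH < 0), strictly decreasing in temperature.
#'
#' @param thermo a \code{\link{duplex_thermo}}.
#' @param temperature_K absolute temperature(s), kelvin.
#' @return association constant(s), 1/M.
#' @export
vant_hoff_K <- function(thermo, temperature_K) {
  stopifnot_finite(temperature_K, "temperature_K")
  if (any(temperature_K <= 0)) stop("temperature must be positive (kelvin)", call. = FALSE)
  stopifnot_finite(thermo$dH, "dH"); stopifnot_finite(thermo$dS, "dS")
  dG <- thermo$dH - temperature_K * (thermo$dS / 1000)
  exp(-dG / (R_KCAL * temperature_K))
}

#' Two-state duplex fraction
#'
#' Fraction of each strand in duplex for a non-self-complementary duplex at
#' equal per-strand totals C: the positive root of K C (1-theta)^2 = theta.
#'
#' @param thermo a \code{\link{duplex_thermo}}.
#' @param temp_C temperature(s), degrees Celsius.
#' @param total_conc per-strand total concentration, M.
#' @return theta in [0, 1], same length as \code{temp_C}.
#' @export
theta_two_state <- function(thermo, temp_C, total_conc) {
  if (total_conc <= 0) stop("total_conc must be positive", call. = FALSE)
  x <- vant_hoff_K(thermo, temp_C + C_TO_K) * total_conc
  # theta = ((2x+1) - sqrt(4x+1)) / (2x), in the cancellation-safe form
  2 * x / (2 * x + 1 + sqrt(4 * x + 1))
}

#' Melting temperature of a two-state duplex
#'
#' Tm is the temperature at which theta = 1/2 under the package's two-state
#' convention, i.e. the solution of K(Tm) * C = 2 for per-strand total C:
#' Tm = dH / (dS + R ln(C/2)) in kelvin.
#'
#' @param thermo a \code{\link{duplex_thermo}} (requires dH < 0, dS < 0).
#' @param total_conc per-strand total concentration, M.
#' @return Tm in degrees Celsius.
#' @export
melting_temperature <- function(thermo, total_conc) {
  if (total_conc <= 0) stop("total_conc must be positive", call. = FALSE)
  tm_K <- thermo$dH / (thermo$dS / 1000 + R_KCAL * log(total_conc / 2))
  tm_C <- tm_K - C_TO_K
  if (!is.finite(tm_C) || tm_C <= 0 || tm_C >= 120) {
    stop(sprintf("no melting temperature in (0, 120) C (got %.1f C)", tm_C), call. = FALSE)
  }
  tm_C
}
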