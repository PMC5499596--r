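# Equilibrium speciation of the donor (EPT) / acceptor (amino) / template
# three-strand system, and amine protonation fractions.
#
# Model: independent two-site binding of donor A and acceptor B to adjacent
# template windows with an optional nearest-duplex cooperativity factor
# omega: [TA] = K_A [T][A], [TB] = K_B [T][B], [TAB] = omega K_A K_B [T][A][B].

#' Default pKa registry for terminal amino nucleotides
#'
#' Reported pKa values: 5'-amino nucleotide 7.8, 3'-amino deoxynucleotide
#' 7.7, 3'-amino ribonucleotide 7.0. Override entries by passing a named
#' vector to functions that accept a pKa, or use this registry directly.
#'
#' @return named numeric vector of pKa values.
#' @export
amine_pka_registry <- function() {
  c(NH2_5p_DNA = 7.8, NH2_3p_DNA = 7.7, NH2_5p_RNA = 7.8, NH2_3p_RNA = 7.0)
}

#' Henderson-Hasselbalch unprotonated fraction
#'
#' The nucleophilic (reactive) population of a terminal amine is its
#' unprotonated fraction 1 / (1 + 10^(pKa - pH)); strictly increasing in pH.
#'
#' @param pKa acid dissociation constant of the protonated amine, in (0, 14).
#' @param pH solution pH, in (0, 14).
#' @return fraction in [0, 1]; vectorized over both arguments.
#' @export
unprotonated_fraction <- function(pKa, pH) {
  stopifnot_finite(pKa, "pKa"); stopifnot_finite(pH, "pH")
  if (any(pKa <= 0 | pKa >= 14)) stop("pKa must lie in (0, 14)", call. = FALSE)
  if (any(pH <= 0 | pH >= 14)) stop("pH must lie in (0, 14)", call. = FALSE)
  1 / (1 + 10^(pKa - pH))
}

#' Reaction conditions for the templated ligation system
#'
#' @param pH solution pH in [0, 14].
#' @param temp_C temperature, degrees Celsius.
#' @param conc_ept donor (EPT) strand total, M.
#' @param conc_amino acceptor (amino) strand total, M.
#' @param conc_template template strand total, M.
#' @param mg_mM Mg2+ concentration, mM (annotation only; no salt correction
#'   is applied).
#' @return an object of class \code{"reaction_conditions"}. Defaults are the
#'   standard assay condition: 4 uM donor, 2 uM acceptor, 4 uM template,
#'   pH 8.0, 25 C, 10 mM Mg2+.
#' @export
reaction_conditions <- function(pH = 8.0, temp_C = 25, conc_ept = 4e-6,
                                conc_amino = 2e-6, conc_template = 4e-6,
                                mg_mM = 10) {
  if (pH < 0 || pH > 14) stop("pH must lie in [0, 14]", call. = FALSE)
  concs <- c(conc_ept = conc_ept, conc_amino = conc_amino, conc_template = conc_template)
  if (any(!is.finite(concs)) || any(concs < 0)) {
    stop("concentrations must be finite and non-negative", call. = FALSE)
  }
  structure(list(pH = pH, temp_C = temp_C, conc_ept = conc_ept,
                 conc_amino = conc_amino, conc_template = conc_template,
                 mg_mM = mg_mM), class = "reaction_conditions")
}

#' @export
print.reaction_conditions <- function(x, ...) {
  cat(sprintf("Conditions: pH %.1f, %.0f C, donor %.2g M, acceptor %.2g M, template %.2g M, Mg2+ %.0f mM\n",
              x$pH, x$temp_C, x$conc_ept, x$conc_amino, x$conc_template, x$mg_mM))
  invisible(x)
}

# Given free template t, eliminate free donor a and free acceptor b in
# closed form (quadratic in b after substituting a(b)).
free_donor_acceptor <- function(t, K_A, K_B, omega, At, Bt) {
  u <- omega * K_A * K_B * t
  fa <- 1 + K_A * t
  fb <- 1 + K_B * t
  if (u == 0) {
    b <- Bt / fb
  } else {
    qa <- u * fb
    qb <- fb * fa + u * (At - Bt)
    qc <- -Bt * fa
    disc <- qb^2 - 4 * qa * qc
    # qc <= 0, so the positive root; cancellation-safe form for qb > 0
    b <- if (qb >= 0) 2 * (-qc) / (qb + sqrt(disc)) else (-qb + sqrt(disc)) / (2 * qa)
  }
  a <- At / (fa + u * b)
  c(a = a, b = b)
}

#' Equilibrium speciation of the three-strand system
#'
#' Solves the mass-balance equilibrium for species {T, A, B, TA, TB, TAB}
#' (template, free donor, free acceptor, the two binary duplexes and the
#' ternary complex) by bisection on the free-template concentration with
#' closed-form elimination of the free probe strands at each step.
#'
#' @param K_A donor.template association constant, 1/M.
#' @param K_B acceptor.template association constant, 1/M.
#' @param cond a \code{\link{reaction_conditions}}.
#' @param cooperativity omega multiplying K_A K_B in the ternary complex
#'   (default 1: independent sites).
#' @param tol relative bisection tolerance on free template (default 1e-12).
#' @param max_iter maximum bisection iterations (default 200).
#' @return an object of class \code{"speciation"} with concentrations (M),
#'   fractional occupancies by reference species, and the maximum relative
#'   mass-balance residual.
#' @export
ternary_fractions <- function(K_A, K_B, cond = reaction_conditions(),
                              cooperativity = 1, tol = 1e-12, max_iter = 200L) {
  if (!is.finite(K_A) || !is.finite(K_B) || K_A < 0 || K_B < 0)
    stop("K_A and K_B must be finite and non-negative", call. = FALSE)
  if (!is.finite(cooperativity) || cooperativity <= 0)
    stop("cooperativity must be positive", call. = FALSE)
  Tt <- cond$conc_template; At <- cond$conc_ept; Bt <- cond$conc_amino
  g <- function(t) {
    ab <- free_donor_acceptor(t, K_A, K_B, cooperativity, At, Bt)
    t * (1 + K_A * ab[["a"]] + K_B * ab[["b"]] +
           cooperativity * K_A * K_B * ab[["a"]] * ab[["b"]]) - Tt
  }
  if (Tt == 0) {
    t <- 0
  } else {
    lo <- 0; hi <- Tt
    iter <- 0L
    while (iter < max_iter) {
      mid <- (lo + hi) / 2
      # stop when the midpoint is no longer representable between the brackets
      if (mid <= lo || mid >= hi || (hi - lo) <= tol * max(lo, .Machine$double.xmin)) break
      if (g(mid) > 0) hi <- mid else lo <- mid
      iter <- iter + 1L
    }
    t <- (lo + hi) / 2
  }
  ab <- free_donor_acceptor(t, K_A, K_B, cooperativity, At, Bt)
  a <- ab[["a"]]; b <- ab[["b"]]
  TA <- K_A * t * a
  TB <- K_B * t * b
  TAB <- cooperativity * K_A * K_B * t * a * b
  rel <- function(total, parts) if (total > 0) abs(total - parts) / total else abs(parts)
  residual <- max(rel(Tt, t + TA + TB + TAB),
                  rel(At, a + TA + TAB),
                  rel(Bt, b + TB + TAB))
  if (residual > 1e-9) {
    stop(sprintf("speciation solver did not converge: relative residual %.3g", residual),
         call. = FALSE)
  }
  totals <- c(template = Tt, donor = At, acceptor = Bt)
  frac_ternary <- vapply(totals, function(tot) if (tot > 0) TAB / tot else 0, numeric(1))
  positive <- totals[totals > 0]
  limiting <- if (length(positive) > 0) names(positive)[which.min(positive)] else "acceptor"
  structure(list(
    free_template = t, free_ept = a, free_amino = b,
    duplex_TA = TA, duplex_TB = TB, ternary_TAB = TAB,
    totals = totals, K_A = K_A, K_B = K_B, cooperativity = cooperativity,
    fractions = frac_ternary, limiting_strand = limiting,
    fraction_limiting = unname(frac_ternary[limiting]),
    residual = residual, cond = cond), class = "speciation")
}

#' Fractional occupancy of a species relative to a reference strand total
#'
#' @param spec a \code{"speciation"} result.
#' @param species one of "ternary_TAB", "duplex_TA", "duplex_TB",
#'   "free_template", "free_ept", "free_amino".
#' @param reference one of "template", "donor", "acceptor", "limiting".
#' @return fraction in [0, 1].
#' @export
fraction_of <- function(spec, species = "ternary_TAB", reference = "limiting") {
  stopifnot(inherits(spec, "speciation"))
  species <- match.arg(species, c("ternary_TAB", "duplex_TA", "duplex_TB",
                                  "free_template", "free_ept", "free_amino"))
  reference <- match.arg(reference, c("template", "donor", "acceptor", "limiting"))
  if (reference == "limiting") reference <- spec$limiting_strand
  tot <- spec$totals[[reference]]
  if (tot <= 0) return(0)
  spec[[species]] / tot
}

#' @export
print.speciation <- function(x, ...) {
  cat("Equilibrium speciation (independent two-site binding)\n")
  cat(sprintf("  K_A = %.4g, K_B = %.4g 1/M, omega = %g\n", x$K_A, x$K_B, x$cooperativity))
  cat(sprintf("  free: T %.3g, A %.3g, B %.3g M\n", x$free_template, x$free_ept, x$free_amino))
  cat(sprintf("  bound: TA %.3g, TB %.3g, TAB %.3g M\n", x$duplex_TA, x$duplex_TB, x$ternary_TAB))
  cat(sprintf("  ternary fraction of limiting strand (%s): %.4f\n",
              x$limiting_strand, x$fraction_limiting))
  cat(sprintf("  mass-balance residual: %.2g (relative)\n", x$residual))
  invisible(x)
}

#' Ternary-complex occupancy report by reference species
#'
#' The headline "fraction in ternary complex" depends on which strand total
#' it is referred to; this report makes the convention explicit by printing
#' all four framings (template, donor, acceptor, limiting strand).
#'
#' @inheritParams ternary_fractions
#' @param digits decimals for the percentage column (half-up rounding).
#' @return a data frame with columns reference, total_M, percent_in_ternary.
#' @export
ternary_occupancy_report <- function(K_A, K_B, cond = reaction_conditions(),
                                     cooperativity = 1, digits = 1) {
  spec <- ternary_fractions(K_A, K_B, cond, cooperativity)
  refs <- c("template", "donor", "acceptor", "limiting")
  pct <- vapply(refs, function(r) 100 * fraction_of(spec, "ternary_TAB", r), numeric(1))
  tot <- c(spec$totals, limiting = unname(spec$totals[spec$limiting_strand]))
  out <- data.frame(reference = refs,
                    total_M = unname(tot[c("template", "donor", "acceptor", "limiting")]),
                    percent_in_ternary = round_half_up(pct, digits),
                    row.names = NULL)
  attr(out, "limiting_strand") <- spec$limiting_strand
  attr(out, "convention") <- "percent of the reference strand's total residing in the full ternary complex"
  out
}
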