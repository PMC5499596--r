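# Forward kinetics of templated EPT ligation.
#
# The ligation flux is pH-gated (Henderson-Hasselbalch unprotonated fraction
# of the acceptor amine), occupancy-gated (quasi-equilibrium ternary-complex
# fraction of the acceptor strand, re-solved as the reaction consumes it) and
# competes with irreversible hydrolysis of the electrophilic
# phosphorothioester: dB/dt = -k_chem * f_unprot * occ(t) * E(t) * B,
# dE/dt = -k_hyd * E.

#' Kinetic parameters for the ligation model
#'
#' @param k_chem intrinsic ligation rate constant within the ternary complex
#'   for the unprotonated amine, 1/min.
#' @param k_hyd EPT hydrolysis rate constant, 1/min.
#' @param pKa pKa of the acceptor's terminal amine (default 7.8, a 5'-amino
#'   nucleotide; see \code{\link{amine_pka_registry}}).
#' @param k_app_override optional: use this apparent rate constant directly,
#'   bypassing the gates.
#' @return an object of class \code{"kinetic_params"}.
#' @export
kinetic_params <- function(k_chem, k_hyd = 0, pKa = 7.8, k_app_override = NULL) {
  rates <- c(k_chem = k_chem, k_hyd = k_hyd)
  if (any(!is.finite(rates)) || any(rates < 0)) {
    stop("rate constants must be finite and non-negative", call. = FALSE)
  }
  if (!is.null(k_app_override) && (!is.finite(k_app_override) || k_app_override < 0)) {
    stop("k_app_override must be finite and non-negative", call. = FALSE)
  }
  structure(list(k_chem = k_chem, k_hyd = k_hyd, pKa = pKa,
                 k_app_override = k_app_override), class = "kinetic_params")
}

#' Assemble a templated-ligation system
#'
#' @param cond a \code{\link{reaction_conditions}}.
#' @param K_A,K_B donor.template and acceptor.template association
#'   constants, 1/M.
#' @param params a \code{\link{kinetic_params}}.
#' @param strands optional list of \code{\link{strand}} objects (donor,
#'   acceptor, template) for annotation.
#' @param template_present if FALSE the predicted ligation flux is exactly
#'   zero (the no-template control).
#' @param cooperativity ternary-complex cooperativity omega (default 1).
#' @param inactive_fraction fraction of the acceptor strand that never
#'   reacts; a phenomenological handle for sub-unity plateaus (default 0).
#' @param hyd_protection factor on the hydrolysis rate of template-bound
#'   EPT: 1 = no protection (hydrolysis equal for bound and free, the
#'   default), 0 = bound EPT fully protected.
#' @return an object of class \code{"ligation_system"}.
#' @export
ligation_system <- function(cond, K_A, K_B, params, strands = NULL,
                            template_present = TRUE, cooperativity = 1,
                            inactive_fraction = 0, hyd_protection = 1) {
  stopifnot(inherits(cond, "reaction_conditions"), inherits(params, "kinetic_params"))
  if (missing(K_A) || missing(K_B) || is.null(K_A) || is.null(K_B)) {
    stop("association constants K_A and K_B must be supplied", call. = FALSE)
  }
  if (inactive_fraction < 0 || inactive_fraction >= 1) {
    stop("inactive_fraction must lie in [0, 1)", call. = FALSE)
  }
  structure(list(cond = cond, K_A = K_A, K_B = K_B, params = params,
                 strands = strands, template_present = isTRUE(template_present),
                 cooperativity = cooperativity,
                 inactive_fraction = inactive_fraction,
                 hyd_protection = hyd_protection), class = "ligation_system")
}

# occupancy of the acceptor strand in the ternary complex at current
# remaining-amino fraction (relative to the acceptor's starting total)
acceptor_occupancy <- function(system, amino_frac = 1) {
  cond <- system$cond
  cond$conc_amino <- cond$conc_amino * amino_frac
  if (cond$conc_amino <= 0) return(0)
  spec <- ternary_fractions(system$K_A, system$K_B, cond, system$cooperativity)
  fraction_of(spec, "ternary_TAB", "acceptor")
}

#' Apparent first-order ligation rate constant at time zero
#'
#' k_app = k_chem x (unprotonated amine fraction at the system's pH) x
#' (ternary-complex occupancy of the acceptor strand at t = 0); exactly 0
#' without template.
#'
#' @param system a \code{\link{ligation_system}}.
#' @return apparent rate constant, 1/min.
#' @export
effective_k_app <- function(system) {
  stopifnot(inherits(system, "ligation_system"))
  if (!system$template_present) return(0)
  p <- system$params
  if (!is.null(p$k_app_override)) return(p$k_app_override)
  f <- unprotonated_fraction(p$pKa, system$cond$pH)
  occ <- acceptor_occupancy(system, 1)
  p$k_chem * f * occ
}

#' Closed-form solution of first-order ligation with competing hydrolysis
#'
#' With a time-decaying rate k0 exp(-k_hyd t) acting on the acceptor,
#' the remaining-acceptor fraction is
#' exp(-(k0/k_hyd) (1 - exp(-k_hyd t))) for k_hyd > 0 and exp(-k0 t) at
#' k_hyd = 0; the plateau yield is 1 - exp(-k0/k_hyd).
#'
#' @param k0 initial apparent ligation rate constant, 1/min.
#' @param k_hyd EPT hydrolysis rate constant, 1/min.
#' @param t time(s), min.
#' @return list with \code{frac_amino_remaining} (same length as t) and
#'   scalar \code{plateau_yield}.
#' @export
closed_form_competing <- function(k0, k_hyd, t) {
  if (k0 < 0 || k_hyd < 0) stop("rate constants must be non-negative", call. = FALSE)
  if (any(t < 0)) stop("times must be non-negative", call. = FALSE)
  if (k_hyd == 0) {
    rem <- exp(-k0 * t)
    plateau <- if (k0 > 0) 1 else 0
  } else {
    rem <- exp((k0 / k_hyd) * expm1(-k_hyd * t))  # expm1 keeps the k_hyd -> 0 limit exact
    plateau <- 1 - exp(-k0 / k_hyd)
  }
  list(frac_amino_remaining = rem, plateau_yield = plateau)
}

#' Simulate a templated-ligation time course
#'
#' Integrates the gated two-state system: the acceptor is consumed at
#' k_chem x f_unprot x occupancy(t) x E(t), where E(t) is the surviving
#' active-EPT fraction (dE/dt = -k_hyd E, hydrolysis applied uniformly to
#' bound and free EPT unless \code{hyd_protection} < 1) and the
#' ternary-complex occupancy is re-solved from the speciation equilibrium as
#' the acceptor is consumed (quasi-equilibrium hybridization).
#'
#' @param system a \code{\link{ligation_system}}.
#' @param times non-decreasing evaluation grid starting at 0, min.
#' @param occupancy NULL to re-solve the speciation equilibrium along the
#'   trajectory (default), or a fixed numeric occupancy in [0, 1] (1 pins
#'   the system in the pseudo-first-order regime).
#' @param rtol,atol integrator tolerances (adaptive lsoda).
#' @return a \code{\link{timecourse}} with provenance "simulated".
#' @export
simulate_ligation <- function(system, times, occupancy = NULL,
                              rtol = 1e-9, atol = 1e-12) {
  stopifnot(inherits(system, "ligation_system"))
  stopifnot_finite(times, "times")
  if (times[1] != 0) stop("time grid must start at t = 0", call. = FALSE)
  if (any(diff(times) < 0)) stop("times must be non-decreasing", call. = FALSE)
  p <- system$params
  f <- unprotonated_fraction(p$pKa, system$cond$pH)
  q <- system$inactive_fraction
  gate0 <- if (!system$template_present) 0 else f
  k_hyd_eff <- function(E, occ_donor) {
    # protection factor g on bound EPT: rate = k_hyd (free + g * bound)
    g <- system$hyd_protection
    p$k_hyd * ((1 - occ_donor) + g * occ_donor)
  }
  occ_fun <- if (!is.null(occupancy)) {
    if (occupancy < 0 || occupancy > 1) stop("fixed occupancy must lie in [0, 1]", call. = FALSE)
    function(amino_frac) occupancy
  } else {
    function(amino_frac) acceptor_occupancy(system, amino_frac)
  }
  deriv <- function(t, y, parms) {
    B <- y[1]; E <- y[2]
    amino_frac <- q + (1 - q) * max(B, 0)
    occ <- occ_fun(amino_frac)
    k_app <- if (!is.null(p$k_app_override) && system$template_present)
      p$k_app_override * E else p$k_chem * gate0 * occ * E
    dB <- -k_app * B
    occ_donor <- if (p$k_hyd > 0 && system$hyd_protection != 1) {
      cond <- system$cond; cond$conc_amino <- cond$conc_amino * amino_frac
      spec <- ternary_fractions(system$K_A, system$K_B, cond, system$cooperativity)
      fraction_of(spec, "ternary_TAB", "donor") + fraction_of(spec, "duplex_TA", "donor")
    } else 0
    dE <- -k_hyd_eff(E, occ_donor) * E
    list(c(dB, dE))
  }
  sol <- deSolve::ode(y = c(B = 1, E = 1), times = times, func = deriv,
                      parms = NULL, method = "lsoda", rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0) {
    stop(sprintf("ODE integration failed (istate %d); try a finer grid or looser tolerances",
                 attr(sol, "istate")[1]), call. = FALSE)
  }
  B <- pmin(pmax(sol[, "B"], 0), 1)
  E <- pmin(pmax(sol[, "E"], 0), 1)
  remaining <- q + (1 - q) * B
  timecourse(time_min = times,
             frac_amino_remaining = remaining,
             frac_product = 1 - remaining,
             frac_ept_active = E,
             provenance = "simulated")
}

#' Simulate hydrolytic decay of the active EPT species
#'
#' Pure first-order loss of the electrophilic phosphorothioester:
#' E(t) = exp(-k_hyd t); half-life ln(2)/k_hyd.
#'
#' @param k_hyd hydrolysis rate constant, 1/min.
#' @param times non-decreasing time grid, min.
#' @return a \code{\link{timecourse}} with a \code{frac_ept_active} column.
#' @export
simulate_ept_decay <- function(k_hyd, times) {
  if (k_hyd < 0) stop("k_hyd must be non-negative", call. = FALSE)
  stopifnot_finite(times, "times")
  timecourse(time_min = times, frac_ept_active = exp(-k_hyd * times),
             provenance = "simulated")
}
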