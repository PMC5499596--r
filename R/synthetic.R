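# Seeded synthetic-data generators emulating the study's raw inputs: nicked
# duplex strand trios, ligation time courses with plateau and noise,
# exponential EPT-stability decays, two-state melting curves and gel-lane
# intensity tables. Defaults reproduce the study conditions: a 10-mer donor
# and 13-mer acceptor on a 23-mer template, 4/2/4 uM totals, hydrolysis
# half-lives in the 6.4-8.9 h regime, association constants near 10^9-10^10
# 1/M at 25 C, and additive Gaussian fraction noise sd 0.02.

#' Noise specification for the generators
#'
#' @param kind "additive_gaussian" (on fractions) or
#'   "multiplicative_gaussian" (relative, on intensities).
#' @param sd standard deviation (unitless for additive-on-fraction, relative
#'   for multiplicative); default 0.02.
#' @param seed optional RNG seed applied by the generator before drawing.
#' @return an object of class \code{"noise_spec"}.
#' @export
noise_spec <- function(kind = c("additive_gaussian", "multiplicative_gaussian"),
                       sd = 0.02, seed = NULL) {
  kind <- match.arg(kind)
  if (!is.finite(sd) || sd < 0) stop("noise sd must be non-negative", call. = FALSE)
  structure(list(kind = kind, sd = sd, seed = seed), class = "noise_spec")
}

# apply noise; clip fractions to [0,1] and count clipped values
apply_noise <- function(x, noise, clip = c(0, 1)) {
  if (!is.null(noise$seed)) set.seed(noise$seed)
  y <- if (noise$sd == 0) x
  else if (noise$kind == "additive_gaussian") x + stats::rnorm(length(x), 0, noise$sd)
  else x * (1 + stats::rnorm(length(x), 0, noise$sd))
  if (is.null(clip)) return(list(x = y, n_clipped = 0L))
  clipped <- y < clip[1] | y > clip[2]
  list(x = pmin(pmax(y, clip[1]), clip[2]), n_clipped = sum(clipped))
}

#' Generate a nicked-duplex strand trio
#'
#' Draws random donor and acceptor sequences and builds the template as the
#' reverse complement of the acceptor followed by the reverse complement of
#' the donor, so the two probes tile the template contiguously with a nick
#' between the donor's reactive 3' end and the acceptor's reactive 5' end.
#'
#' @param donor_len donor length, nt (default 10).
#' @param acceptor_len acceptor length, nt (default 13).
#' @param seed RNG seed (deterministic trio for a fixed seed).
#' @param alphabet "DNA" or "RNA".
#' @return list with \code{donor} (3'-EPT), \code{acceptor} (5'-NH2,
#'   FAM-labelled) and \code{template} strands.
#' @export
gen_strand_trio <- function(donor_len = 10, acceptor_len = 13, seed = NULL,
                            alphabet = c("DNA", "RNA")) {
  alphabet <- match.arg(alphabet)
  if (donor_len < 2 || acceptor_len < 2) stop("strand lengths must be >= 2", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  letters_nt <- if (alphabet == "DNA") c("A", "C", "G", "T") else c("A", "C", "G", "U")
  draw <- function(n) paste(sample(letters_nt, n, replace = TRUE), collapse = "")
  donor_seq <- draw(donor_len)
  acceptor_seq <- draw(acceptor_len)
  template_seq <- paste0(revcomp(acceptor_seq, alphabet), revcomp(donor_seq, alphabet))
  list(
    donor = strand("donor", donor_seq, role = "donor", end_chem = "EPT_3p",
                   alphabet = alphabet),
    acceptor = strand("acceptor", acceptor_seq, role = "acceptor", end_chem = "NH2_5p",
                      alphabet = alphabet, label = "FAM"),
    template = strand("template", template_seq, role = "template", end_chem = "none",
                      alphabet = alphabet))
}

#' Generate a ligation time course
#'
#' Mean curve: product fraction = plateau_cap x (1 - remaining fraction of
#' the competing-hydrolysis closed form); noise per the \code{noise_spec},
#' with the t = 0 product pinned to exactly 0 and fractions clipped to
#' [0, 1] (clips counted in the result's \code{n_clipped} attribute).
#'
#' @param k0 initial apparent ligation rate constant, 1/min.
#' @param k_hyd EPT hydrolysis rate constant, 1/min.
#' @param plateau_cap maximal attainable product fraction in (0, 1]
#'   (phenomenological unreactive-subpopulation cap; default 1).
#' @param times time grid, min, starting at 0.
#' @param noise a \code{\link{noise_spec}}.
#' @return a \code{\link{timecourse}} with provenance "synthetic_fixture".
#' @export
gen_ligation_timecourse <- function(k0, k_hyd = 0, plateau_cap = 1,
                                    times = seq(0, 120, by = 10),
                                    noise = noise_spec(sd = 0)) {
  if (k0 < 0 || k_hyd < 0) stop("rate constants must be non-negative", call. = FALSE)
  if (plateau_cap <= 0 || plateau_cap > 1) stop("plateau_cap must lie in (0, 1]", call. = FALSE)
  if (times[1] != 0) stop("time grid must start at 0", call. = FALSE)
  cf <- closed_form_competing(k0, k_hyd, times)
  product <- plateau_cap * (1 - cf$frac_amino_remaining)
  noised <- apply_noise(product, noise)
  product <- noised$x
  product[times == 0] <- 0
  timecourse(time_min = times,
             frac_amino_remaining = 1 - product,
             frac_product = product,
             frac_ept_active = exp(-k_hyd * times),
             provenance = "synthetic_fixture",
             n_clipped = noised$n_clipped)
}

#' Generate an EPT-stability decay curve
#'
#' Exponential decay at the stated half-life plus noise; emulates the
#' hydrolytic-stability assay (half-lives of 6.4-8.9 h, i.e. 384-534 min,
#' in the default regime).
#'
#' @param half_life_min decay half-life, min (e.g. 486 = 8.1 h).
#' @param times time grid, min.
#' @param noise a \code{\link{noise_spec}}.
#' @return a \code{\link{timecourse}} with a \code{frac_ept_active} column.
#' @export
gen_decay_timecourse <- function(half_life_min = 486,
                                 times = seq(0, 1440, by = 120),
                                 noise = noise_spec(sd = 0)) {
  if (!is.finite(half_life_min) || half_life_min <= 0) {
    stop("half_life_min must be positive", call. = FALSE)
  }
  frac <- exp(-log(2) / half_life_min * times)
  noised <- apply_noise(frac, noise)
  timecourse(time_min = times, frac_ept_active = noised$x,
             provenance = "synthetic_fixture", n_clipped = noised$n_clipped)
}

#' Generate a two-state melting curve
#'
#' theta(T) under the package's two-state convention for the given (dH, dS)
#' and per-strand concentration, plus noise. The default thermodynamics give
#' K(25 C) in the 10^9-10^10 1/M regime typical of the study's 10-13-mer
#' probe-template duplexes.
#'
#' @param thermo a \code{\link{duplex_thermo}} (default dH = -70 kcal/mol,
#'   dS = -190 cal/(mol K), K(25 C) ~ 7e9 1/M).
#' @param conc per-strand total concentration, M.
#' @param t_grid temperature grid, degrees Celsius, strictly increasing.
#' @param noise a \code{\link{noise_spec}}.
#' @return a \code{\link{melting_curve}} (with an \code{n_clipped} attribute).
#' @export
gen_melting_curve <- function(thermo = duplex_thermo(-70, -190), conc = 4e-6,
                              t_grid = seq(10, 90, by = 2),
                              noise = noise_spec(sd = 0)) {
  theta <- theta_two_state(thermo, t_grid, conc)
  noised <- apply_noise(theta, noise)
  curve <- melting_curve(t_grid, noised$x, conc)
  attr(curve, "n_clipped") <- noised$n_clipped
  curve
}

#' Generate a gel-lane intensity table
#'
#' Per-lane (i_remaining, i_product) band intensities whose ratio is
#' centred on the true yield; emulates PAGE fluorescence quantitation.
#'
#' @param true_yields vector of true product-yield fractions in [0, 1], one
#'   per lane.
#' @param total_intensity total lane fluorescence, arbitrary units.
#' @param noise a \code{\link{noise_spec}} (multiplicative recommended; each
#'   band is perturbed independently).
#' @return data frame with columns lane, i_remaining, i_product.
#' @export
gen_gel_table <- function(true_yields, total_intensity = 1000,
                          noise = noise_spec("multiplicative_gaussian", sd = 0)) {
  if (any(true_yields < 0 | true_yields > 1)) {
    stop("true yields must lie in [0, 1]", call. = FALSE)
  }
  i_rem <- (1 - true_yields) * total_intensity
  i_prod <- true_yields * total_intensity
  both <- apply_noise(c(i_rem, i_prod), noise, clip = c(0, Inf))
  n <- length(true_yields)
  data.frame(lane = seq_len(n),
             i_remaining = both$x[seq_len(n)],
             i_product = both$x[n + seq_len(n)])
}
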