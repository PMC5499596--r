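# Internal helpers shared across modules.

# Gas constant in kcal/(mol*K); all enthalpies are kcal/mol, entropies cal/(mol*K).
R_KCAL <- 1.9872e-3

C_TO_K <- 273.15

#' Round half away from zero to a given number of decimals
#'
#' Base \code{round()} rounds half to even; printed percentages in the
#' chemical literature are conventionally rounded half-up, so comparisons
#' against published integer percentages use this rule.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 0).
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

stopifnot_finite <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop(sprintf("'%s' must be finite numeric", name), call. = FALSE)
  }
  invisible(x)
}

# FNV-1a 32-bit hash of a string; used to stamp config hashes into file
# headers without an external digest dependency.
fnv1a32 <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 2166136261
  for (b in bytes) {
    lo <- h %% 256                      # xor touches only the low byte
    h <- h - lo + bitwXor(as.integer(lo), b)
    # 32-bit modular multiply split into 16-bit halves (stays below 2^53)
    hi <- h %/% 65536
    lo2 <- h %% 65536
    h <- (lo2 * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%08x", h)
}

#' Reverse complement of a nucleic-acid sequence
#'
#' @param seq character scalar, 5'->3' over A/C/G/T (DNA) or A/C/G/U (RNA).
#' @param alphabet "DNA" or "RNA".
#' @return the reverse complement, 5'->3'.
#' @export
revcomp <- function(seq, alphabet = c("DNA", "RNA")) {
  alphabet <- match.arg(alphabet)
  comp <- if (alphabet == "DNA") chartr("ACGT", "TGCA", seq) else chartr("ACGU", "UGCA", seq)
  paste(rev(strsplit(comp, "")[[1]]), collapse = "")
}

check_alphabet <- function(seq, alphabet = "DNA") {
  letters_ok <- if (alphabet == "DNA") c("A", "C", "G", "T") else c("A", "C", "G", "U")
  ch <- strsplit(seq, "")[[1]]
  bad <- which(!ch %in% letters_ok)
  if (length(bad) > 0) {
    stop(sprintf("ambiguous or invalid base '%s' at position %d (alphabet %s)",
                 ch[bad[1]], bad[1], alphabet), call. = FALSE)
  }
  invisible(seq)
}
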