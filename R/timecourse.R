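# Time-course container and its delimited-text I/O.
#
# CSV schema: header `time_min,frac_amino_remaining,frac_product[,frac_ept_active]`
# with optional leading comment lines starting with '#'. Files written by the
# package embed the package version, seed and a config hash in those comments.

#' Reaction time-course container
#'
#' A data frame of sampled reaction progress. At every time point the
#' remaining-acceptor fraction plus the product fraction cannot exceed 1
#' (within 1e-9), and the t = 0 row must have zero product.
#'
#' @param time_min sampling times, min, non-decreasing.
#' @param frac_amino_remaining C/C0 of the acceptor strand, in [0, 1].
#' @param frac_product ligated-product fraction, in [0, 1].
#' @param frac_ept_active optional surviving active-EPT fraction, in [0, 1].
#' @param provenance one of "simulated", "closed_form", "synthetic_fixture",
#'   "user".
#' @param n_clipped count of noise-clipped values (generators record it).
#' @return a data frame of class \code{"timecourse"}.
#' @export
timecourse <- function(time_min, frac_amino_remaining = NULL, frac_product = NULL,
                       frac_ept_active = NULL,
                       provenance = c("user", "simulated", "closed_form", "synthetic_fixture"),
                       n_clipped = 0L) {
  provenance <- match.arg(provenance)
  stopifnot_finite(time_min, "time_min")
  if (any(diff(time_min) < 0)) stop("times must be non-decreasing", call. = FALSE)
  cols <- list(time_min = time_min)
  for (nm in c("frac_amino_remaining", "frac_product", "frac_ept_active")) {
    v <- get(nm)
    if (!is.null(v)) {
      stopifnot_finite(v, nm)
      if (length(v) != length(time_min)) stop(sprintf("'%s' length mismatch", nm), call. = FALSE)
      if (any(v < -1e-12 | v > 1 + 1e-12)) {
        stop(sprintf("'%s' values must lie in [0, 1]", nm), call. = FALSE)
      }
      cols[[nm]] <- pmin(pmax(v, 0), 1)
    }
  }
  if (is.null(cols$frac_amino_remaining) && is.null(cols$frac_ept_active)) {
    stop("a time course needs frac_amino_remaining and/or frac_ept_active", call. = FALSE)
  }
  if (!is.null(cols$frac_amino_remaining) && !is.null(cols$frac_product)) {
    if (any(cols$frac_amino_remaining + cols$frac_product > 1 + 1e-9)) {
      stop("frac_amino_remaining + frac_product exceeds 1", call. = FALSE)
    }
    if (any(time_min == 0) && any(cols$frac_product[time_min == 0] != 0)) {
      stop("frac_product must be exactly 0 at t = 0", call. = FALSE)
    }
  }
  out <- as.data.frame(cols)
  attr(out, "provenance") <- provenance
  attr(out, "n_clipped") <- as.integer(n_clipped)
  class(out) <- c("timecourse", "data.frame")
  out
}

#' @export
print.timecourse <- function(x, ...) {
  cat(sprintf("Time course (%s): %d points, t = %g-%g min%s\n",
              attr(x, "provenance"), nrow(x), min(x$time_min), max(x$time_min),
              if (isTRUE(attr(x, "n_clipped") > 0))
                sprintf(", %d noise-clipped values", attr(x, "n_clipped")) else ""))
  print.data.frame(utils::head(as.data.frame(x), 8), row.names = FALSE)
  if (nrow(x) > 8) cat(sprintf("  ... %d more rows\n", nrow(x) - 8))
  invisible(x)
}

#' @export
plot.timecourse <- function(x, ...) {
  ycols <- intersect(c("frac_amino_remaining", "frac_product", "frac_ept_active"), names(x))
  graphics::matplot(x$time_min, as.matrix(x[ycols]), type = "b", pch = 16,
                    xlab = "time (min)", ylab = "fraction", ylim = c(0, 1), ...)
  graphics::legend("right", legend = ycols, col = seq_along(ycols),
                   lty = seq_along(ycols), pch = 16, bty = "n", cex = 0.8)
  invisible(x)
}

#' Write a time course to CSV
#'
#' Numeric payload is written at 12+ significant digits so write/read
#' round-trips are lossless at that precision; a comment header records the
#' package version, seed and config hash.
#'
#' @param tc a \code{\link{timecourse}}.
#' @param path output file path.
#' @param seed seed to record in the header (NA if none applies).
#' @return the path, invisibly.
#' @export
write_timecourse <- function(tc, path, seed = NA) {
  stopifnot(inherits(tc, "timecourse"))
  df <- as.data.frame(tc)
  payload <- vapply(df, function(col) format(col, digits = 15, scientific = FALSE,
                                             trim = TRUE), character(nrow(df)))
  payload <- matrix(payload, nrow = nrow(df))
  cfg <- paste(names(df), collapse = ",")
  header <- c(
    sprintf("# eptlig %s", as.character(utils::packageVersion("eptlig"))),
    sprintf("# seed: %s", as.character(seed)),
    sprintf("# config_hash: %s", fnv1a32(paste(cfg, attr(tc, "provenance"), sep = "|"))),
    sprintf("# provenance: %s", attr(tc, "provenance")))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  writeLines(paste(names(df), collapse = ","), con)
  writeLines(apply(payload, 1, paste, collapse = ","), con)
  invisible(path)
}

#' Read a time course from CSV
#'
#' Accepts LF or CRLF line endings and '#' comment lines; validates the
#' schema and reports the offending row on malformed input.
#'
#' @param path input file path.
#' @return a \code{\link{timecourse}} with provenance "user".
#' @export
read_timecourse <- function(path) {
  if (!file.exists(path)) stop(sprintf("input file '%s' does not exist", path), call. = FALSE)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!"time_min" %in% names(df)) {
    stop(sprintf("'%s': missing required column time_min", path), call. = FALSE)
  }
  known <- c("time_min", "frac_amino_remaining", "frac_product", "frac_ept_active")
  fcols <- intersect(known[-1], names(df))
  if (length(fcols) == 0) {
    stop(sprintf("'%s': no fraction column (frac_amino_remaining/frac_product/frac_ept_active)",
                 path), call. = FALSE)
  }
  for (nm in c("time_min", fcols)) {
    v <- suppressWarnings(as.numeric(df[[nm]]))
    bad <- which(!is.finite(v))
    if (length(bad) > 0) {
      stop(sprintf("'%s': non-numeric value in column %s at data row %d", path, nm, bad[1]),
           call. = FALSE)
    }
    neg <- if (nm == "time_min") which(v < 0) else which(v < 0 | v > 1)
    if (length(neg) > 0) {
      stop(sprintf("'%s': out-of-range value in column %s at data row %d", path, nm, neg[1]),
           call. = FALSE)
    }
    df[[nm]] <- v
  }
  if (any(diff(df$time_min) < 0)) {
    stop(sprintf("'%s': times decrease at data row %d", path,
                 which(diff(df$time_min) < 0)[1] + 1), call. = FALSE)
  }
  do.call(timecourse, c(as.list(df[c("time_min", fcols)]), provenance = "user"))
}
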