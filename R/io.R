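# File I/O beyond time courses: FASTA strand sets with a JSON metadata
# sidecar, melting-curve CSV and gel-lane CSV.

#' Write strands to FASTA with a JSON metadata sidecar
#'
#' Sequences go to FASTA; role, end chemistry, alphabet and label (which
#' FASTA cannot carry) go to \code{<path>.json}.
#'
#' @param strands list of \code{\link{strand}} objects.
#' @param path FASTA output path.
#' @return the FASTA path, invisibly.
#' @export
write_strands <- function(strands, path) {
  seqs <- lapply(strands, function(s) strsplit(s$sequence, "")[[1]])
  ids <- vapply(strands, function(s) s$id, character(1))
  seqinr::write.fasta(seqs, names = ids, file.out = path)
  meta <- lapply(strands, function(s) {
    list(id = s$id, role = s$role, end_chem = s$end_chem,
         alphabet = s$alphabet, label = s$label)
  })
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' Read strands from FASTA plus JSON sidecar
#'
#' @param path FASTA path; metadata is read from \code{<path>.json} when
#'   present, otherwise all strands default to role "template" with no end
#'   chemistry.
#' @return list of \code{\link{strand}} objects.
#' @export
read_strands <- function(path) {
  if (!file.exists(path)) stop(sprintf("input file '%s' does not exist", path), call. = FALSE)
  fa <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE)
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else NULL
  lapply(seq_along(fa), function(i) {
    id <- names(fa)[i]
    m <- if (!is.null(meta)) Filter(function(x) identical(x$id, id), meta) else list()
    m <- if (length(m) > 0) m[[1]] else list()
    strand(id = id, sequence = toupper(as.character(fa[[i]])),
           role = if (!is.null(m$role)) m$role else "template",
           end_chem = if (!is.null(m$end_chem)) m$end_chem else "none",
           alphabet = if (!is.null(m$alphabet)) m$alphabet else "DNA",
           label = m$label)
  })
}

#' Write a melting curve to CSV
#'
#' Header \code{temp_C,frac_duplex}; a comment header records the package
#' version, seed, per-strand concentration and config hash.
#'
#' @param curve a \code{\link{melting_curve}}.
#' @param path output path.
#' @param seed seed to record (NA if none).
#' @return the path, invisibly.
#' @export
write_melting_curve <- function(curve, path, seed = NA) {
  stopifnot(inherits(curve, "melting_curve"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# eptlig %s", as.character(utils::packageVersion("eptlig"))),
               sprintf("# seed: %s", as.character(seed)),
               sprintf("# total_conc_M: %.12g", curve$total_conc),
               sprintf("# config_hash: %s",
                       fnv1a32(sprintf("melt|%.12g|%d", curve$total_conc,
                                       length(curve$temp_C))))), con)
  writeLines("temp_C,frac_duplex", con)
  writeLines(sprintf("%s,%s", format(curve$temp_C, digits = 15, trim = TRUE),
                     format(curve$theta, digits = 15, trim = TRUE)), con)
  invisible(path)
}

#' Read a melting curve from CSV
#'
#' @param path CSV with header \code{temp_C,frac_duplex}; the per-strand
#'   concentration is taken from a \code{# total_conc_M:} comment unless
#'   given explicitly.
#' @param total_conc per-strand total concentration, M (overrides the file
#'   header).
#' @return a \code{\link{melting_curve}}.
#' @export
read_melting_curve <- function(path, total_conc = NULL) {
  if (!file.exists(path)) stop(sprintf("input file '%s' does not exist", path), call. = FALSE)
  if (is.null(total_conc)) {
    hdr <- grep("^#", readLines(path, n = 20), value = TRUE)
    m <- grep("total_conc_M:", hdr, value = TRUE)
    if (length(m) == 1) total_conc <- as.numeric(sub(".*total_conc_M:\\s*", "", m))
  }
  if (is.null(total_conc) || !is.finite(total_conc)) {
    stop("per-strand concentration not found: pass total_conc or include a '# total_conc_M:' header",
         call. = FALSE)
  }
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("temp_C", "frac_duplex") %in% names(df))) {
    stop(sprintf("'%s': melting curve needs columns temp_C, frac_duplex", path), call. = FALSE)
  }
  melting_curve(as.numeric(df$temp_C), as.numeric(df$frac_duplex), total_conc)
}

#' Read a gel-lane intensity table
#'
#' @param path CSV with columns \code{lane, i_remaining, i_product}.
#' @return data frame with those columns, numeric.
#' @export
read_gel_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("input file '%s' does not exist", path), call. = FALSE)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("lane", "i_remaining", "i_product")
  if (!all(need %in% names(df))) {
    stop(sprintf("'%s': gel table needs columns %s", path, paste(need, collapse = ", ")),
         call. = FALSE)
  }
  df[need]
}
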