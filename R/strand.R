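# Strand objects: an oligonucleotide with an end-chemistry role in the
# nicked-duplex ligation system (donor carries the electrophilic
# phosphorothioester, acceptor the amino nucleophile, template neither).

END_CHEMISTRIES <- c("none", "PS_5p", "PS_3p", "EPT_5p", "EPT_3p", "NH2_5p", "NH2_3p")
REACTIVE_ENDS <- c("EPT_5p", "EPT_3p", "NH2_5p", "NH2_3p")
STRAND_ROLES <- c("donor", "acceptor", "template")

#' Construct an oligonucleotide strand
#'
#' A strand couples a 5'->3' sequence with its role in the templated-ligation
#' system and its terminal chemistry. The donor strand must carry an
#' electrophilic phosphorothioester (EPT) end, the acceptor an amino (NH2)
#' end, and the template no reactive end.
#'
#' @param id character identifier.
#' @param sequence character scalar, 5'->3', over A/C/G/T (DNA) or A/C/G/U (RNA).
#' @param role one of "donor", "acceptor", "template".
#' @param end_chem one of "none", "PS_5p", "PS_3p", "EPT_5p", "EPT_3p",
#'   "NH2_5p", "NH2_3p".
#' @param alphabet "DNA" or "RNA".
#' @param label optional fluorophore tag (e.g. "FAM").
#' @param ome_2p optional logical vector flagging 2'-O-methyl residues
#'   (RNA only); recycled to the sequence length.
#' @return an object of class \code{"ept_strand"}.
#' @export
strand <- function(id, sequence, role, end_chem = "none",
                   alphabet = c("DNA", "RNA"), label = NULL, ome_2p = NULL) {
  alphabet <- match.arg(alphabet)
  role <- match.arg(role, STRAND_ROLES)
  end_chem <- match.arg(end_chem, END_CHEMISTRIES)
  sequence <- toupper(sequence)
  check_alphabet(sequence, alphabet)
  n_reactive <- sum(end_chem %in% REACTIVE_ENDS)
  if (n_reactive > 1) stop("a strand carries at most one reactive end", call. = FALSE)
  if (role == "donor" && !end_chem %in% c("EPT_5p", "EPT_3p"))
    stop("donor strand must carry an EPT end", call. = FALSE)
  if (role == "acceptor" && !end_chem %in% c("NH2_5p", "NH2_3p"))
    stop("acceptor strand must carry an NH2 end", call. = FALSE)
  if (role == "template" && end_chem %in% REACTIVE_ENDS)
    stop("template strand must not carry a reactive end", call. = FALSE)
  if (!is.null(ome_2p)) {
    if (alphabet != "RNA") stop("2'-OMe flags apply to RNA strands only", call. = FALSE)
    ome_2p <- rep_len(as.logical(ome_2p), nchar(sequence))
  }
  structure(list(id = id, sequence = sequence, role = role, end_chem = end_chem,
                 alphabet = alphabet, label = label, ome_2p = ome_2p),
            class = "ept_strand")
}

#' @export
print.ept_strand <- function(x, ...) {
  cat(sprintf("<strand %s> %s-mer %s, role=%s, end=%s%s\n",
              x$id, nchar(x$sequence), x$alphabet, x$role, x$end_chem,
              if (!is.null(x$label)) paste0(", label=", x$label) else ""))
  cat("  5'-", x$sequence, "-3'\n", sep = "")
  invisible(x)
}

#' @export
as.character.ept_strand <- function(x, ...) x$sequence
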