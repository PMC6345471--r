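# IUPAC nucleotide ambiguity codes and small sequence utilities shared by the
# consensus/primer machinery and the simulator.

IUPAC_CODES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# base-set -> code, keyed by the sorted concatenation of the bases
.IUPAC_BY_SET <- local({
  keys <- vapply(IUPAC_CODES, function(b) paste(sort(b), collapse = ""), "")
  stats::setNames(names(IUPAC_CODES), keys)
})

.IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N", `-` = "-"
)

ALIGNMENT_ALPHABET <- c(names(IUPAC_CODES), "-")

#' IUPAC code covering a set of bases
#'
#' @param bases character vector drawn from A, C, G, T.
#' @return single IUPAC character (`"N"` for an empty set).
#' @keywords internal
iupac_code <- function(bases) {
  bases <- unique(bases)
  if (length(bases) == 0L) return("N")
  stopifnot(all(bases %in% c("A", "C", "G", "T")))
  unname(.IUPAC_BY_SET[paste(sort(bases), collapse = "")])
}

#' Bases encoded by an IUPAC character
#' @keywords internal
iupac_bases <- function(code) {
  b <- IUPAC_CODES[[code]]
  if (is.null(b)) stop("invalid IUPAC code: ", code, call. = FALSE)
  b
}

#' Reverse complement of an IUPAC nucleotide string
#'
#' Handles all 15 ambiguity codes and the gap character.
#'
#' @param x a single nucleotide string (IUPAC alphabet).
#' @return the reverse complement, same length.
#' @examples
#' revcomp_iupac("GGWGAT")
#' @export
revcomp_iupac <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  ch <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  bad <- setdiff(ch, names(.IUPAC_COMPLEMENT))
  if (length(bad)) stop("invalid IUPAC character(s): ", paste(bad, collapse = ", "), call. = FALSE)
  paste(rev(unname(.IUPAC_COMPLEMENT[ch])), collapse = "")
}

#' Degeneracy of an IUPAC primer
#'
#' The number of distinct exact sequences a degenerate primer encodes: the
#' product over positions of the cardinality of each position's IUPAC code.
#'
#' @param primer a single IUPAC nucleotide string (no gaps).
#' @return integer degeneracy.
#' @examples
#' primer_degeneracy("GGWGATGAYCAAATTTAYAAGT") # 8
#' @export
primer_degeneracy <- function(primer) {
  stopifnot(is.character(primer), length(primer) == 1L, nzchar(primer))
  ch <- strsplit(toupper(primer), "", fixed = TRUE)[[1]]
  bad <- setdiff(ch, names(IUPAC_CODES))
  if (length(bad)) stop("invalid IUPAC character(s): ", paste(bad, collapse = ", "), call. = FALSE)
  card <- vapply(ch, function(c) length(IUPAC_CODES[[c]]), 1L)
  as.integer(prod(card))
}
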