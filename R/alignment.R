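# Species-labelled alignments: construction, FASTA I/O and the summary
# statistics (variable sites, parsimony-informative sites, base composition)
# usually quoted for barcode datasets.

#' Construct a species-labelled alignment
#'
#' The universal input object of the package: an aligned set of barcode
#' sequences in which every record carries a species label. Columns are
#' addressed 1-based and ranges are inclusive.
#'
#' @param sequences character vector of aligned sequences (equal length,
#'   IUPAC alphabet plus `-`).
#' @param ids unique record identifiers.
#' @param species species label per record (non-empty).
#' @return an object of class `species_alignment` with fields `id`, `species`,
#'   `seq` and `n_columns`.
#' @export
species_alignment <- function(sequences, ids, species) {
  stopifnot(is.character(sequences), is.character(ids), is.character(species))
  n <- length(sequences)
  if (n < 2L) stop("an alignment needs at least 2 records", call. = FALSE)
  if (length(ids) != n || length(species) != n)
    stop("sequences, ids and species must have equal length", call. = FALSE)
  if (anyDuplicated(ids))
    stop("duplicate record ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  if (any(!nzchar(species)) || anyNA(species))
    stop("every record needs a non-empty species label", call. = FALSE)
  sequences <- toupper(sequences)
  len <- nchar(sequences)
  if (length(unique(len)) != 1L) {
    tab <- table(len)
    modal <- if (sum(tab == max(tab)) > 1L) len[1L] else
      as.integer(names(which.max(tab)))
    off <- ids[len != modal]
    stop("alignment error: unequal sequence lengths; offending record(s): ",
         paste(off, collapse = ", "), call. = FALSE)
  }
  chars <- unique(strsplit(paste(sequences, collapse = ""), "", fixed = TRUE)[[1]])
  bad <- setdiff(chars, ALIGNMENT_ALPHABET)
  if (length(bad))
    stop("invalid alignment character(s): ", paste(bad, collapse = ", "), call. = FALSE)
  structure(
    list(id = ids, species = species, seq = sequences, n_columns = len[1]),
    class = "species_alignment"
  )
}

#' @export
print.species_alignment <- function(x, ...) {
  cat("Species alignment: ", length(x$id), " sequences x ", x$n_columns,
      " columns, ", length(unique(x$species)), " species\n", sep = "")
  invisible(x)
}

#' Number of records in an alignment
#' @param aln a `species_alignment`.
#' @export
n_records <- function(aln) {
  stopifnot(inherits(aln, "species_alignment"))
  length(aln$id)
}

#' Alignment as a character matrix (records x columns)
#' @param aln a `species_alignment`.
#' @return character matrix with row names = record ids.
#' @export
alignment_matrix <- function(aln) {
  stopifnot(inherits(aln, "species_alignment"))
  m <- do.call(rbind, strsplit(aln$seq, "", fixed = TRUE))
  rownames(m) <- aln$id
  m
}

#' Slice alignment columns
#'
#' @param aln a `species_alignment`.
#' @param start,end 1-based inclusive column range.
#' @return a `species_alignment` over columns `start..end`.
#' @export
slice_alignment <- function(aln, start, end) {
  stopifnot(inherits(aln, "species_alignment"))
  if (start < 1L || end > aln$n_columns || start > end)
    stop("invalid column range [", start, ", ", end, "]", call. = FALSE)
  species_alignment(substr(aln$seq, start, end), aln$id, aln$species)
}

#' Read a species-labelled FASTA alignment
#'
#' Headers are parsed into a record id and a species label. Under the default
#' scheme the header is split on `|`; the first token is the id and the second
#' the species binomial (e.g. `x1|Panulirus_homarus`). GenBank/BOLD exports
#' vary, so the delimiter and field indices are configurable.
#'
#' @param path FASTA file (wrapped or unwrapped lines).
#' @param delim header field delimiter (default `"|"`).
#' @param id_field,species_field 1-based token indices of the id and species.
#' @return a `species_alignment`.
#' @export
read_alignment <- function(path, delim = "|", id_field = 1L, species_field = 2L) {
  if (!file.exists(path)) stop("input error: no such file: ", path, call. = FALSE)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("input error: ", conditionMessage(e), call. = FALSE))
  if (length(set) == 0L) stop("input error: empty FASTA file: ", path, call. = FALSE)
  headers <- names(set)
  toks <- strsplit(headers, delim, fixed = TRUE)
  need <- max(id_field, species_field)
  short <- vapply(toks, length, 1L) < need
  if (any(short))
    stop("labelling error: header(s) lack delimiter '", delim, "': ",
         paste(utils::head(headers[short], 3L), collapse = "; "), call. = FALSE)
  ids <- vapply(toks, `[[`, "", id_field)
  sp <- vapply(toks, `[[`, "", species_field)
  species_alignment(unname(as.character(set)), ids, sp)
}

#' Write a species-labelled alignment as FASTA
#'
#' Headers are `id<delim>species`; sequence lines wrap at `width` columns.
#'
#' @param aln a `species_alignment`.
#' @param path output file.
#' @param delim header delimiter (default `"|"`).
#' @param width line-wrap width (default 80).
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path, delim = "|", width = 80L) {
  stopifnot(inherits(aln, "species_alignment"))
  set <- Biostrings::BStringSet(aln$seq)
  names(set) <- paste(aln$id, aln$species, sep = delim)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Alignment summary statistics
#'
#' Counts of variable (V) and parsimony-informative (Pi) columns and the
#' pooled nucleotide composition, the summary usually reported for barcode
#' alignments. A column is variable when it holds at least two distinct
#' unambiguous bases; parsimony-informative when at least two bases each occur
#' in at least two sequences. Gaps and ambiguity codes never contribute to the
#' state tallies, and composition is pooled over all unambiguous bases.
#'
#' @param aln a `species_alignment`.
#' @return an `alignment_stats` object with fields `V`, `Pi`, `composition`,
#'   `n_sequences`, `n_columns`.
#' @export
alignment_stats <- function(aln) {
  stopifnot(inherits(aln, "species_alignment"))
  m <- alignment_matrix(aln)
  bases <- c("A", "C", "G", "T")
  counts <- sapply(bases, function(b) colSums(m == b))  # n_columns x 4
  if (aln$n_columns == 1L) counts <- matrix(counts, nrow = 1L, dimnames = list(NULL, bases))
  n_states <- rowSums(counts > 0L)
  V <- sum(n_states >= 2L)
  Pi <- sum(rowSums(counts >= 2L) >= 2L)
  tot <- colSums(counts)
  comp <- tot / sum(tot)
  structure(
    list(V = as.integer(V), Pi = as.integer(Pi), composition = comp,
         n_sequences = length(aln$id), n_columns = aln$n_columns),
    class = "alignment_stats"
  )
}

#' @export
print.alignment_stats <- function(x, digits = 4L, ...) {
  cat("Alignment: ", x$n_sequences, " sequences x ", x$n_columns, " columns\n", sep = "")
  cat("Variable sites (V):              ", x$V, "\n", sep = "")
  cat("Parsimony-informative sites (Pi):", x$Pi, "\n")
  cat("Base composition: ",
      paste(sprintf("%s=%.*f", names(x$composition), digits, x$composition), collapse = " "),
      "\n", sep = "")
  invisible(x)
}

#' Write alignment statistics as TSV
#' @param stats an `alignment_stats` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_stats_tsv <- function(stats, path) {
  stopifnot(inherits(stats, "alignment_stats"))
  df <- data.frame(
    statistic = c("n_sequences", "n_columns", "V", "Pi",
                  paste0("freq_", names(stats$composition))),
    value = c(stats$n_sequences, stats$n_columns, stats$V, stats$Pi,
              unname(stats$composition))
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
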