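# Kimura 2-parameter pairwise distances, the distance matrix object and the
# intra/inter-specific partition feeding the barcode-gap analysis.
#
# d = -1/2 ln(1 - 2P - Q) - 1/4 ln(1 - 2Q), with P and Q the transition and
# transversion fractions over sites where both sequences carry an unambiguous
# base (pairwise deletion). Pairs with too few usable sites, or with a
# non-positive log argument (saturation), are reported as missing (NA) rather
# than raising, so a window scan over degraded data stays total.

.PURINES <- c("A", "G")

# 4x4 substitution class lookup over A,C,G,T codes 1..4: 0 same, 1 transition,
# 2 transversion
.K2P_CLASS <- local({
  b <- c("A", "C", "G", "T")
  cls <- matrix(2L, 4L, 4L, dimnames = list(b, b))
  diag(cls) <- 0L
  cls["A", "G"] <- cls["G", "A"] <- 1L
  cls["C", "T"] <- cls["T", "C"] <- 1L
  cls
})

# encode sequences as integers 1..4 (A,C,G,T), NA for gaps/ambiguity
.encode_acgt <- function(seqs) {
  m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  code <- match(m, c("A", "C", "G", "T"))
  matrix(code, nrow = nrow(m))
}

.k2p_from_counts <- function(ts, tv, usable, min_sites) {
  P <- ts / usable
  Q <- tv / usable
  a1 <- 1 - 2 * P - Q
  a2 <- 1 - 2 * Q
  d <- ifelse(a1 > 0 & a2 > 0, -0.5 * log(pmax(a1, .Machine$double.xmin)) -
                0.25 * log(pmax(a2, .Machine$double.xmin)), NA_real_)
  d[usable < min_sites] <- NA_real_
  list(d = d, P = P, Q = Q,
       saturated = usable >= min_sites & !(a1 > 0 & a2 > 0),
       below_min = usable < min_sites)
}

#' Kimura 2-parameter distance between two aligned sequences
#'
#' Computed with pairwise deletion: only sites where both sequences carry an
#' unambiguous base (A/C/G/T) are compared. Returns `NA` (with a warning) when
#' fewer than `min_sites` sites are usable or when a log argument is
#' non-positive (saturation).
#'
#' @param seq_a,seq_b aligned sequences of equal length (strings).
#' @param min_sites minimum usable sites; default half the compared length.
#' @return the K2P distance (or `NA`), with attributes `P`, `Q` (transition and
#'   transversion fractions) and `usable` (compared sites).
#' @examples
#' k2p_pair("AACGTACGTACGTACGTACG", "AACGTACGTACGTACGTACG")  # 0
#' @export
k2p_pair <- function(seq_a, seq_b, min_sites = NULL) {
  stopifnot(is.character(seq_a), is.character(seq_b),
            length(seq_a) == 1L, length(seq_b) == 1L)
  if (nchar(seq_a) != nchar(seq_b))
    stop("input error: sequences differ in length (", nchar(seq_a), " vs ",
         nchar(seq_b), ")", call. = FALSE)
  L <- nchar(seq_a)
  if (is.null(min_sites)) min_sites <- ceiling(0.5 * L)
  a <- .encode_acgt(toupper(seq_a))[1L, ]
  b <- .encode_acgt(toupper(seq_b))[1L, ]
  ok <- !is.na(a) & !is.na(b)
  usable <- sum(ok)
  cls <- .K2P_CLASS[cbind(a[ok], b[ok])]
  res <- .k2p_from_counts(sum(cls == 1L), sum(cls == 2L), usable, min_sites)
  if (res$below_min)
    warning("fewer than ", min_sites, " usable sites (", usable, "); distance is NA",
            call. = FALSE)
  else if (res$saturated)
    warning("K2P distance undefined (saturation); distance is NA", call. = FALSE)
  structure(res$d, P = res$P, Q = res$Q, usable = usable)
}

#' K2P distance matrix for an alignment
#'
#' All pairwise K2P distances under pairwise deletion. Saturated pairs and
#' pairs with fewer than `min_sites_frac * n_columns` usable sites are `NA`;
#' their counts are carried on the object and summarised once as a warning.
#'
#' @param aln a `species_alignment`.
#' @param min_sites_frac minimum usable sites as a fraction of the compared
#'   region length (default 0.5).
#' @return a `k2p_dist` object: fields `d` (symmetric matrix, zero diagonal,
#'   `NA` = missing), `labels`, `species`, `min_sites`, `n_saturated`,
#'   `n_below_min`.
#' @export
k2p_matrix <- function(aln, min_sites_frac = 0.5) {
  stopifnot(inherits(aln, "species_alignment"))
  code <- .encode_acgt(aln$seq)
  n <- nrow(code)
  min_sites <- ceiling(min_sites_frac * aln$n_columns)
  d <- matrix(0, n, n, dimnames = list(aln$id, aln$id))
  n_sat <- 0L
  n_low <- 0L
  for (i in seq_len(n - 1L)) {
    ai <- code[i, ]
    for (j in (i + 1L):n) {
      bj <- code[j, ]
      ok <- !is.na(ai) & !is.na(bj)
      cls <- .K2P_CLASS[cbind(ai[ok], bj[ok])]
      res <- .k2p_from_counts(sum(cls == 1L), sum(cls == 2L), sum(ok), min_sites)
      d[i, j] <- d[j, i] <- res$d
      n_sat <- n_sat + (res$saturated && !res$below_min)
      n_low <- n_low + res$below_min
    }
  }
  if (n_sat + n_low > 0L)
    warning(n_sat, " saturated and ", n_low,
            " low-overlap pair(s) set to NA in the K2P matrix", call. = FALSE)
  structure(
    list(d = d, labels = aln$id, species = aln$species,
         min_sites = min_sites, n_saturated = n_sat, n_below_min = n_low,
         deletion = "pairwise"),
    class = "k2p_dist"
  )
}

#' @export
print.k2p_dist <- function(x, ...) {
  n <- length(x$labels)
  off <- x$d[lower.tri(x$d)]
  cat("K2P distance matrix: ", n, " taxa (", x$deletion, " deletion, min ",
      x$min_sites, " sites)\n", sep = "")
  cat("  mean off-diagonal distance: ",
      format(mean(off, na.rm = TRUE), digits = 4L), "\n", sep = "")
  if (anyNA(off))
    cat("  missing pairs: ", sum(is.na(off)), " (", x$n_saturated, " saturated, ",
        x$n_below_min, " low overlap)\n", sep = "")
  invisible(x)
}

#' @export
as.matrix.k2p_dist <- function(x, ...) x$d

#' Partition pairwise distances into intra- and interspecific classes
#'
#' Every non-missing off-diagonal pair is assigned to the intraspecific class
#' when the two records share a species label, otherwise to the interspecific
#' class. Missing pairs land in neither.
#'
#' @param m a `k2p_dist` object.
#' @return a `distance_partition`: fields `intra`, `inter` (numeric vectors)
#'   and `n_missing`.
#' @export
partition_distances <- function(m) {
  stopifnot(inherits(m, "k2p_dist"))
  if (is.null(m$species) || anyNA(m$species))
    stop("species labels required to partition distances", call. = FALSE)
  lt <- which(lower.tri(m$d), arr.ind = TRUE)
  vals <- m$d[lt]
  same <- m$species[lt[, 1L]] == m$species[lt[, 2L]]
  keep <- !is.na(vals)
  structure(
    list(intra = vals[keep & same], inter = vals[keep & !same],
         n_missing = sum(!keep)),
    class = "distance_partition"
  )
}

#' @export
print.distance_partition <- function(x, ...) {
  cat("Distance partition: ", length(x$intra), " intraspecific, ",
      length(x$inter), " interspecific pairs", sep = "")
  if (x$n_missing > 0L) cat(" (", x$n_missing, " missing)", sep = "")
  cat("\n")
  invisible(x)
}

#' Write a distance matrix as square TSV
#' @param m a `k2p_dist`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_distance_tsv <- function(m, path) {
  stopifnot(inherits(m, "k2p_dist"))
  utils::write.table(m$d, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' Write a distance matrix in PHYLIP format
#'
#' Square PHYLIP-style distance file; missing values are written as `-1`.
#'
#' @param m a `k2p_dist`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_distance_phylip <- function(m, path) {
  stopifnot(inherits(m, "k2p_dist"))
  d <- m$d
  d[is.na(d)] <- -1
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(d)), con)
  for (i in seq_len(nrow(d))) {
    writeLines(paste(formatC(m$labels[i], width = -10L),
                     paste(sprintf("%.6f", d[i, ]), collapse = " ")), con)
  }
  invisible(path)
}
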