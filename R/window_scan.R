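# The sliding-window scan: enumerate windows along the alignment, score each
# by (1) mean K2P distance, (2) proportion of zero non-conspecific distances,
# (3) congruence of the window NJ tree with the full-length reference tree;
# keep the top two per window length by sum of ranks; crown the winner by
# K-score / RF comparison against the reference tree.
#
# Window distances are obtained from cumulative per-pair transition,
# transversion and usable-site counts over columns, so each window's K2P
# matrix costs O(pairs) regardless of window length.

#' Enumerate sliding windows
#'
#' For each length L, windows start at 1, 1+step, ... while `start+L-1` fits
#' in the alignment: `floor((n_columns - L) / step) + 1` windows per length.
#'
#' @param n_columns alignment width.
#' @param lengths window lengths in bp (default 100, 110, ..., 230).
#' @param step shift between successive windows in bp (default 10).
#' @return data.frame with columns `start`, `length`, `end` (1-based,
#'   inclusive).
#' @export
enumerate_windows <- function(n_columns, lengths = seq(100L, 230L, by = 10L),
                              step = 10L) {
  stopifnot(n_columns >= 1L, all(lengths >= 1L), step >= 1L)
  if (max(lengths) > n_columns)
    stop("input error: window length ", max(lengths), " exceeds alignment width ",
         n_columns, call. = FALSE)
  out <- do.call(rbind, lapply(sort(unique(as.integer(lengths))), function(L) {
    starts <- seq.int(1L, n_columns - L + 1L, by = step)
    data.frame(start = starts, length = L, end = starts + L - 1L)
  }))
  rownames(out) <- NULL
  out
}

# Cumulative per-pair counts: list with ii/jj pair indices, conspecific flags,
# and (n_pairs x n_columns+1) cumulative transition/transversion/usable
# matrices. Column range [s, e] counts are cum[, e + 1] - cum[, s].
k2p_profile <- function(aln) {
  code <- .encode_acgt(aln$seq)
  n <- nrow(code)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  ii <- pairs[, 1L]; jj <- pairs[, 2L]
  np <- nrow(pairs)
  nc <- aln$n_columns
  cts <- matrix(0L, np, nc); ctv <- matrix(0L, np, nc); cus <- matrix(0L, np, nc)
  for (p in seq_len(np)) {
    a <- code[ii[p], ]; b <- code[jj[p], ]
    ok <- !is.na(a) & !is.na(b)
    cls <- integer(nc)
    cls[ok] <- .K2P_CLASS[cbind(a[ok], b[ok])]
    cts[p, ] <- cumsum(cls == 1L & ok)
    ctv[p, ] <- cumsum(cls == 2L & ok)
    cus[p, ] <- cumsum(ok)
  }
  list(ii = ii, jj = jj, n = n,
       conspecific = aln$species[ii] == aln$species[jj],
       labels = aln$id, species = aln$species,
       cts = cbind(0L, cts), ctv = cbind(0L, ctv), cus = cbind(0L, cus))
}

# K2P distance vector (per pair) for columns [s, e] from a profile
.profile_window_d <- function(profile, s, e, min_sites_frac = 0.5) {
  ts <- profile$cts[, e + 1L] - profile$cts[, s]
  tv <- profile$ctv[, e + 1L] - profile$ctv[, s]
  us <- profile$cus[, e + 1L] - profile$cus[, s]
  .k2p_from_counts(ts, tv, us, ceiling(min_sites_frac * (e - s + 1L)))$d
}

# expand a per-pair distance vector to a symmetric matrix
.pairvec_to_matrix <- function(profile, d) {
  n <- profile$n
  m <- matrix(0, n, n, dimnames = list(profile$labels, profile$labels))
  m[cbind(profile$ii, profile$jj)] <- d
  m[cbind(profile$jj, profile$ii)] <- d
  m
}

.window_tree <- function(profile, d) {
  m <- .pairvec_to_matrix(profile, d)
  usable <- rownames(m)
  while (anyNA(m) && nrow(m) > 3L) {
    worst <- which.max(rowSums(is.na(m)))
    m <- m[-worst, -worst, drop = FALSE]
  }
  if (anyNA(m) || nrow(m) < 3L) return(NULL)
  tr <- ape::nj(m)
  tr$edge.length <- pmax(tr$edge.length, 0)
  tr
}

.score_one_window <- function(profile, s, e, ref_tree, species_map,
                              min_sites_frac = 0.5) {
  d <- .profile_window_d(profile, s, e, min_sites_frac)
  ok <- !is.na(d)
  noncon <- ok & !profile$conspecific
  mean_k2p <- if (any(ok)) mean(d[ok]) else NA_real_
  prop_zero_noncon <- if (any(noncon)) mean(d[noncon] == 0) else NA_real_
  prop_zero_cells <- if (any(ok)) mean(d[ok] == 0) else NA_real_
  tr <- .window_tree(profile, d)
  if (is.null(tr)) {
    con <- list(congruence = NA_real_, shallow = NA_real_)
    flag <- "no_tree"
  } else {
    con <- clade_congruence(ref_tree, tr, species_map)
    flag <- ""
  }
  data.frame(start = s, length = e - s + 1L, end = e,
             mean_k2p = mean_k2p, prop_zero_noncon = prop_zero_noncon,
             prop_zero_cells = prop_zero_cells,
             congruence = con$congruence, congruence_shallow = con$shallow,
             flag = flag, stringsAsFactors = FALSE)
}

#' Score a single window against the full-length reference tree
#'
#' Slices columns `[start, end]`, computes the window K2P matrix, the three
#' selection criteria and the NJ-tree congruence statistics.
#'
#' @param aln a `species_alignment`.
#' @param window one row of \code{\link{enumerate_windows}} (or any list with
#'   `start` and `end`).
#' @param ref_tree reference NJ tree built from the full-length alignment.
#' @param min_sites_frac passed to the window K2P computation.
#' @param profile optional precomputed `k2p_profile(aln)` (for repeated calls).
#' @return one-row data.frame: `start`, `length`, `end`, `mean_k2p`,
#'   `prop_zero_noncon`, `prop_zero_cells`, `congruence`,
#'   `congruence_shallow`, `flag` (`"no_tree"` when fewer than 3 usable rows).
#' @export
score_window <- function(aln, window, ref_tree, min_sites_frac = 0.5,
                         profile = NULL) {
  stopifnot(inherits(aln, "species_alignment"))
  s <- as.integer(window$start); e <- as.integer(window$end)
  if (s < 1L || e > aln$n_columns || s > e)
    stop("invalid window [", s, ", ", e, "]", call. = FALSE)
  if (is.null(profile)) profile <- k2p_profile(aln)
  species_map <- stats::setNames(aln$species, aln$id)
  .score_one_window(profile, s, e, ref_tree, species_map, min_sites_frac)
}

#' Score every window of a sliding-window scan
#'
#' @inheritParams score_window
#' @param lengths,step window grid (see \code{\link{enumerate_windows}}).
#' @return data.frame of per-window scores (one row per window).
#' @export
scan_windows <- function(aln, ref_tree, lengths = seq(100L, 230L, by = 10L),
                         step = 10L, min_sites_frac = 0.5, profile = NULL) {
  stopifnot(inherits(aln, "species_alignment"))
  wins <- enumerate_windows(aln$n_columns, lengths, step)
  if (is.null(profile)) profile <- k2p_profile(aln)
  species_map <- stats::setNames(aln$species, aln$id)
  rows <- lapply(seq_len(nrow(wins)), function(k)
    .score_one_window(profile, wins$start[k], wins$end[k], ref_tree,
                      species_map, min_sites_frac))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Select the top candidate windows per length
#'
#' Within each window length, every window receives a composite rank: the sum
#' of its ranks by mean K2P distance (descending), proportion of zero
#' non-conspecific distances (ascending) and tree congruence (descending),
#' with average ranks on ties (missing congruence ranks worst). The
#' `per_length` best windows per length are kept and named
#' `"<length>_a"`, `"<length>_b"`, ... in rank order; composite ties go to the
#' smaller start.
#'
#' @param scores data.frame from \code{\link{scan_windows}}.
#' @param per_length candidates retained per length (default 2).
#' @return subset of `scores` with added `composite_rank` and `name` columns.
#' @export
select_candidates <- function(scores, per_length = 2L) {
  stopifnot(is.data.frame(scores), nrow(scores) > 0L, per_length >= 1L)
  pieces <- lapply(split(scores, scores$length), function(g) {
    con <- ifelse(is.na(g$congruence), -Inf, g$congruence)
    comp <- rank(-g$mean_k2p, ties.method = "average") +
      rank(g$prop_zero_noncon, ties.method = "average") +
      rank(-con, ties.method = "average")
    g$composite_rank <- comp
    g <- g[order(comp, g$start), , drop = FALSE]
    k <- min(per_length, nrow(g))
    if (k < per_length)
      warning("only ", nrow(g), " window(s) of length ", g$length[1L],
              "; keeping all", call. = FALSE)
    g <- g[seq_len(k), , drop = FALSE]
    g$name <- paste0(g$length, "_", letters[seq_len(k)])
    g
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Crown the best fragment by tree comparison
#'
#' For each candidate window, builds the window NJ tree and compares it with
#' the full-length reference tree; the winner minimises the K-score, with
#' ties broken by lower RF distance, then greater window length, then smaller
#' start.
#'
#' @param candidates data.frame from \code{\link{select_candidates}}.
#' @inheritParams score_window
#' @return a `best_fragment` object: `window` (name/start/length/end),
#'   `comparison` (a `tree_comparison`), and `table` — all candidates with
#'   `k_score`, `K`, `rf`, `rank_by_kscore`, `rank_by_rf`.
#' @export
select_best <- function(candidates, aln, ref_tree, min_sites_frac = 0.5,
                        profile = NULL) {
  stopifnot(is.data.frame(candidates), nrow(candidates) >= 1L)
  if (is.null(profile)) profile <- k2p_profile(aln)
  comps <- lapply(seq_len(nrow(candidates)), function(k) {
    d <- .profile_window_d(profile, candidates$start[k], candidates$end[k],
                           min_sites_frac)
    tr <- .window_tree(profile, d)
    if (is.null(tr))
      return(list(k_score = Inf, K = NA_real_, rf = NA_integer_))
    if (length(tr$tip.label) < length(ref_tree$tip.label))
      k_score(ape::keep.tip(ref_tree, tr$tip.label), tr)
    else k_score(ref_tree, tr)
  })
  tab <- candidates
  tab$k_score <- vapply(comps, function(x) x$k_score, 0)
  tab$K <- vapply(comps, function(x) as.numeric(x$K), 0)
  tab$rf <- vapply(comps, function(x) as.integer(x$rf), 0L)
  tab$rank_by_kscore <- rank(tab$k_score, ties.method = "min")
  tab$rank_by_rf <- rank(tab$rf, ties.method = "min")
  ord <- order(tab$k_score, tab$rf, -tab$length, tab$start)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  win <- tab[1L, ]
  structure(
    list(window = list(name = win$name, start = win$start,
                       length = win$length, end = win$end),
         comparison = comps[[ord[1L]]],
         table = tab),
    class = "best_fragment"
  )
}

#' @export
print.best_fragment <- function(x, ...) {
  cat("Best mini-barcode fragment: ", x$window$name, " (columns ",
      x$window$start, "-", x$window$end, ", ", x$window$length, " bp)\n",
      sep = "")
  cat("  K-score = ", format(x$comparison$k_score, digits = 5L),
      ", RF = ", x$comparison$rf, " vs full-length reference tree\n", sep = "")
  invisible(x)
}

#' Sliding-window mini-barcode scan
#'
#' The end-to-end fragment estimator: builds the full-length K2P matrix and
#' reference NJ tree, scores every window on the length/step grid, keeps the
#' top `per_length` windows per length by composite rank, and selects the
#' final fragment by K-score (then RF) against the reference tree.
#'
#' @param aln a `species_alignment`.
#' @param lengths window lengths in bp (default 100-230 by 10).
#' @param step window shift in bp (default 10).
#' @param per_length candidates kept per length (default 2).
#' @param min_sites_frac minimum usable-site fraction for a pairwise distance.
#' @return a `minibar_scan` object: `scores` (all windows), `candidates`,
#'   `best` (a `best_fragment`), `ref_tree`, `stats`
#'   (\code{\link{alignment_stats}}), and the call parameters.
#' @seealso \code{\link{run_full_design}} for the full design workflow
#'   including gap analysis and primer design.
#' @export
minibar_scan <- function(aln, lengths = seq(100L, 230L, by = 10L), step = 10L,
                         per_length = 2L, min_sites_frac = 0.5) {
  stopifnot(inherits(aln, "species_alignment"))
  full_m <- k2p_matrix(aln, min_sites_frac)
  ref_tree <- nj_tree(full_m, na_action = "drop")
  profile <- k2p_profile(aln)
  scores <- scan_windows(aln, ref_tree, lengths, step, min_sites_frac, profile)
  candidates <- select_candidates(scores, per_length)
  best <- select_best(candidates, aln, ref_tree, min_sites_frac, profile)
  structure(
    list(scores = scores, candidates = candidates, best = best,
         ref_tree = ref_tree, full_matrix = full_m,
         stats = alignment_stats(aln),
         params = list(lengths = lengths, step = step, per_length = per_length,
                       min_sites_frac = min_sites_frac)),
    class = "minibar_scan"
  )
}

#' @export
print.minibar_scan <- function(x, ...) {
  cat("Mini-barcode sliding-window scan\n")
  cat("  windows scored: ", nrow(x$scores), " (lengths ",
      min(x$params$lengths), "-", max(x$params$lengths), " bp, step ",
      x$params$step, ")\n", sep = "")
  cat("  candidates retained: ", nrow(x$candidates), "\n", sep = "")
  print(x$best)
  invisible(x)
}

#' @export
summary.minibar_scan <- function(object, ...) {
  cat("Mini-barcode sliding-window scan\n\n")
  print(object$stats)
  cat("\nCandidate fragments (ranked by K-score vs reference tree):\n")
  cols <- c("name", "start", "end", "mean_k2p", "prop_zero_noncon",
            "congruence", "k_score", "rf")
  tab <- object$best$table[, cols]
  tab$mean_k2p <- round(tab$mean_k2p, 4L)
  tab$prop_zero_noncon <- round(tab$prop_zero_noncon, 4L)
  tab$congruence <- round(tab$congruence, 3L)
  tab$k_score <- round(tab$k_score, 4L)
  print(tab, row.names = FALSE)
  invisible(object)
}

#' @export
plot.minibar_scan <- function(x, ...) {
  sc <- x$scores
  mid <- (sc$start + sc$end) / 2
  graphics::plot(mid, sc$mean_k2p, col = factor(sc$length), pch = 16L,
                 cex = 0.6, xlab = "alignment position (window midpoint)",
                 ylab = "mean K2P distance",
                 main = "Sliding-window scan", ...)
  w <- x$best$window
  graphics::rect(w$start, graphics::par("usr")[3L], w$end,
                 graphics::par("usr")[4L], border = NA,
                 col = grDevices::adjustcolor("red", 0.15))
  graphics::legend("topright", legend = "selected fragment", fill =
                     grDevices::adjustcolor("red", 0.15), bty = "n")
  invisible(x)
}

#' Write the per-window score table as TSV
#' @param scores data.frame from \code{\link{scan_windows}} (or the
#'   `candidates` table).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_scores_tsv <- function(scores, path) {
  utils::write.table(scores, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
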