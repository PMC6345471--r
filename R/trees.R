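# Neighbor-joining trees from K2P matrices and the two tree-comparison
# statistics used to arbitrate between candidate fragments: the
# Robinson-Foulds symmetric difference and the K-score (branch-length-aware
# dissimilarity after least-squares rescaling of the comparison tree onto the
# reference).

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (via \code{\link[ape]{nj}}). Missing cells are
#' either an error (default) or handled by greedily dropping the taxon
#' involved in the most missing pairs until the matrix is complete
#' (`na_action = "drop"`, with a warning). Negative branch-length estimates
#' are clamped to zero; the pre-clamp values are kept in the
#' `"pre_clamp_lengths"` attribute.
#'
#' @param m a `k2p_dist` object or a symmetric numeric matrix with dimnames.
#' @param na_action `"error"` or `"drop"`.
#' @return an unrooted `phylo` tree. Attribute `"dropped"` lists any taxa
#'   removed under `na_action = "drop"`.
#' @export
nj_tree <- function(m, na_action = c("error", "drop")) {
  na_action <- match.arg(na_action)
  d <- if (inherits(m, "k2p_dist")) m$d else as.matrix(m)
  if (is.null(rownames(d))) stop("distance matrix needs taxon labels", call. = FALSE)
  dropped <- character(0)
  if (anyNA(d)) {
    if (na_action == "error") {
      idx <- which(is.na(d) & upper.tri(d), arr.ind = TRUE)
      pairs <- apply(utils::head(idx, 5L), 1L, function(r)
        paste0(rownames(d)[r[1]], "~", colnames(d)[r[2]]))
      stop("input error: missing distances for pair(s): ",
           paste(pairs, collapse = ", "),
           if (nrow(idx) > 5L) " ..." else "", call. = FALSE)
    }
    while (anyNA(d)) {
      worst <- which.max(rowSums(is.na(d)))
      dropped <- c(dropped, rownames(d)[worst])
      d <- d[-worst, -worst, drop = FALSE]
    }
    warning("dropped ", length(dropped), " taxa with missing distances: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  if (nrow(d) < 3L)
    stop("input error: need at least 3 taxa with complete distances", call. = FALSE)
  tr <- ape::nj(d)
  pre <- tr$edge.length
  if (any(pre < 0)) tr$edge.length <- pmax(pre, 0)
  attr(tr, "pre_clamp_lengths") <- pre
  attr(tr, "dropped") <- dropped
  tr
}

# Bipartitions of an unrooted tree with branch lengths.
#
# Each edge splits the leaves in two; a bipartition is stored under a
# canonical key (the side NOT containing the alphabetically first leaf,
# sorted, '\x1f'-joined). `small` holds the labels of the smaller side (used
# for species-level "shallow" congruence); `trivial` marks terminal splits.
tree_bipartitions <- function(tree, include_trivial = FALSE) {
  stopifnot(inherits(tree, "phylo"))
  if (ape::is.rooted(tree)) tree <- ape::unroot(tree)
  n <- length(tree$tip.label)
  tr <- stats::reorder(tree, "postorder")
  tips <- vector("list", n + tr$Nnode)
  for (i in seq_len(n)) tips[[i]] <- i
  parents <- tr$edge[, 1L]
  children <- tr$edge[, 2L]
  for (k in seq_along(parents))
    tips[[parents[k]]] <- c(tips[[parents[k]]], tips[[children[k]]])
  labs <- tree$tip.label
  ref <- labs[order(labs)][1L]
  keys <- character(length(parents))
  small <- vector("list", length(parents))
  trivial <- logical(length(parents))
  for (k in seq_along(parents)) {
    below <- labs[tips[[children[k]]]]
    side <- if (ref %in% below) setdiff(labs, below) else below
    keys[k] <- paste(sort(side), collapse = "\x1f")
    nb <- length(below)
    small[[k]] <- if (nb <= n - nb) below else setdiff(labs, below)
    trivial[k] <- min(nb, n - nb) <= 1L
  }
  out <- list(key = keys, length = tr$edge.length, small = small, trivial = trivial)
  if (!include_trivial) {
    keep <- !trivial
    out <- list(key = keys[keep], length = tr$edge.length[keep],
                small = small[keep], trivial = trivial[keep])
  }
  out
}

.check_same_leaves <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("input error: trees have different leaf sets", call. = FALSE)
}

#' Robinson-Foulds symmetric difference
#'
#' The number of non-trivial bipartitions present in exactly one of the two
#' unrooted trees (an even integer; 0 iff identical topologies).
#'
#' @param t1,t2 `phylo` trees over the same leaf set.
#' @return integer RF distance.
#' @export
rf_distance <- function(t1, t2) {
  .check_same_leaves(t1, t2)
  b1 <- unique(tree_bipartitions(t1)$key)
  b2 <- unique(tree_bipartitions(t2)$key)
  as.integer(sum(!(b1 %in% b2)) + sum(!(b2 %in% b1)))
}

#' K-score between a reference and a comparison tree
#'
#' Every bipartition of either tree (terminal branches included) is paired by
#' identity of the underlying leaf split; a split absent from one tree enters
#' with branch length 0. With reference lengths \eqn{b_i} and comparison
#' lengths \eqn{b'_i}, the comparison tree is rescaled by the least-squares
#' factor \eqn{K = \sum b_i b'_i / \sum b'^2_i} and the K-score is
#' \eqn{\sqrt{\sum (b_i - K b'_i)^2}}. It is 0 exactly when the comparison
#' tree is a rescaling of the reference, and grows with both topological and
#' branch-length disagreement.
#'
#' @param ref,comp `phylo` trees over the same leaf set.
#' @return a `tree_comparison` object: `k_score`, `K` (`NA` when the
#'   comparison tree has all-zero branches), `rf`, `n_shared`, `n_unshared`
#'   (non-trivial split counts).
#' @export
k_score <- function(ref, comp) {
  .check_same_leaves(ref, comp)
  br <- tree_bipartitions(ref, include_trivial = TRUE)
  bc <- tree_bipartitions(comp, include_trivial = TRUE)
  ref_len <- tapply(br$length, br$key, sum)
  comp_len <- tapply(bc$length, bc$key, sum)
  keys <- union(names(ref_len), names(comp_len))
  b <- ifelse(keys %in% names(ref_len), ref_len[keys], 0)
  bp <- ifelse(keys %in% names(comp_len), comp_len[keys], 0)
  denom <- sum(bp^2)
  if (denom > 0) {
    K <- sum(b * bp) / denom
    ks <- sqrt(sum((b - K * bp)^2))
  } else {
    K <- NA_real_
    ks <- sqrt(sum(b^2))
  }
  r1 <- unique(tree_bipartitions(ref)$key)
  r2 <- unique(tree_bipartitions(comp)$key)
  structure(
    list(k_score = ks, K = K, rf = rf_distance(ref, comp),
         n_shared = sum(r1 %in% r2),
         n_unshared = sum(!(r1 %in% r2)) + sum(!(r2 %in% r1))),
    class = "tree_comparison"
  )
}

#' @export
print.tree_comparison <- function(x, ...) {
  cat("Tree comparison: K-score = ", format(x$k_score, digits = 5L),
      " (K = ", format(x$K, digits = 5L), "), RF = ", x$rf,
      " [", x$n_shared, " shared / ", x$n_unshared, " unshared splits]\n",
      sep = "")
  invisible(x)
}

#' Fraction of reference bipartitions recovered by a comparison tree
#'
#' `congruence` is the proportion of the reference tree's non-trivial
#' bipartitions present in the comparison tree; `shallow` restricts the
#' reference set to species-level splits (those whose smaller side is a set of
#' conspecific individuals), the clades that matter for barcode
#' identification. When the comparison tree covers fewer leaves, the
#' reference is pruned to the shared set first.
#'
#' @param ref reference `phylo` tree.
#' @param comp comparison `phylo` tree (leaf set a subset of `ref`'s).
#' @param species named character vector mapping leaf label to species.
#' @return list with `congruence` and `shallow` (either may be `NA` when no
#'   qualifying reference split exists).
#' @export
clade_congruence <- function(ref, comp, species) {
  if (!all(comp$tip.label %in% ref$tip.label))
    stop("input error: comparison tree has leaves absent from the reference",
         call. = FALSE)
  if (length(comp$tip.label) < length(ref$tip.label))
    ref <- ape::keep.tip(ref, comp$tip.label)
  rb <- tree_bipartitions(ref)
  cb <- unique(tree_bipartitions(comp)$key)
  if (length(rb$key) == 0L) return(list(congruence = NA_real_, shallow = NA_real_))
  hit <- rb$key %in% cb
  con <- mean(hit)
  sp_level <- vapply(rb$small, function(s) length(unique(species[s])) == 1L, TRUE)
  shallow <- if (any(sp_level)) mean(hit[sp_level]) else NA_real_
  list(congruence = con, shallow = shallow)
}

#' Write a tree in Newick format
#' @param tree a `phylo`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tree_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a Newick tree
#' @param path Newick file.
#' @return a `phylo`.
#' @export
read_tree_newick <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("input error: could not parse Newick file: ", path, call. = FALSE)
  tr
}
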