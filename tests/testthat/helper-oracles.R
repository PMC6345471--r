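# Shared fixtures and independent oracles used across the suite. Oracles are
# deliberately written from first principles (string/character arithmetic,
# enumeration) so they never share code with the implementation they check.

# brute-force K2P from two strings: explicit per-site classification and a
# direct evaluation of the closed form
bf_k2p <- function(a, b) {
  ca <- strsplit(toupper(a), "")[[1]]
  cb <- strsplit(toupper(b), "")[[1]]
  pur <- c("A", "G"); pyr <- c("C", "T")
  use <- ca %in% c(pur, pyr) & cb %in% c(pur, pyr)
  n <- sum(use)
  ts <- sum(use & ((ca %in% pur & cb %in% pur) | (ca %in% pyr & cb %in% pyr)) & ca != cb)
  tv <- sum(use & ((ca %in% pur & cb %in% pyr) | (ca %in% pyr & cb %in% pur)))
  P <- ts / n; Q <- tv / n
  if (1 - 2 * P - Q <= 0 || 1 - 2 * Q <= 0) return(NA_real_)
  -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)
}

random_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# small alignment from explicit sequences, labelled x1..xn / two species
tiny_alignment <- function(seqs, species = NULL) {
  n <- length(seqs)
  if (is.null(species)) species <- rep(c("Genus_a", "Genus_b"), length.out = n)
  species_alignment(seqs, paste0("x", seq_len(n)), species)
}

# random unrooted binary tree with positive branch lengths
random_tree <- function(n, min_len = 0.05, max_len = 0.3) {
  tr <- ape::rtree(n, rooted = FALSE, br = function(k) stats::runif(k, min_len, max_len))
  tr$tip.label <- paste0("t", seq_len(n))
  tr
}

# quartet split implied by the four-point condition on a distance matrix:
# returns the pair grouped with taxon `q[1]`, or NA on ties
quartet_from_distances <- function(d, q) {
  s_ab <- d[q[1], q[2]] + d[q[3], q[4]]
  s_ac <- d[q[1], q[3]] + d[q[2], q[4]]
  s_ad <- d[q[1], q[4]] + d[q[2], q[3]]
  s <- c(s_ab, s_ac, s_ad)
  if (sum(s == min(s)) > 1L) return(NA_character_)
  c(q[2], q[3], q[4])[which.min(s)]
}

# quartet split realised by a tree, read off its path-length distances
# (independent of any bipartition code in the package)
quartet_from_tree <- function(tree, q) {
  quartet_from_distances(ape::cophenetic.phylo(tree), q)
}
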