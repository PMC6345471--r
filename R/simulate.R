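# Seeded generator of species-structured barcode alignments: clusters of
# near-identical conspecific sequences, divergent between species, with one
# planted hypervariable window and conserved primer flanks immediately around
# it. Substitutions follow a single-step K2P process (transition with
# probability kappa/(kappa+2), else a uniform transversion); per-site
# substitution probabilities are calibrated numerically so that the expected
# pairwise K2P distance over the whole alignment matches the requested
# intra- and interspecific targets.

#' Simulation configuration
#'
#' Defaults describe a 658-column COI-like barcode: a 230 bp hypervariable
#' window at columns 109-338 evolving 3x faster than background, 80 bp
#' conserved flanks (0.2x) immediately up- and downstream of it, and
#' background rate elsewhere. Species sit on a star phylogeny; individuals
#' radiate from their species ancestor.
#'
#' @param n_species number of species (default 20).
#' @param n_individuals individuals per species (default 3).
#' @param n_columns alignment width in bp (default 658).
#' @param planted_window hypervariable column range (default `c(109, 338)`).
#' @param flank_width width of each conserved flank adjoining the window
#'   (default 80).
#' @param rate_flank,rate_window,rate_background region rate multipliers
#'   (defaults 0.2, 3.0, 1.0).
#' @param d_inter expected interspecific K2P distance (default 0.15).
#' @param d_intra expected intraspecific K2P distance (default 0.005).
#' @param kappa transition/transversion rate ratio (default 2).
#' @param n_rate per-site probability of masking a base as `N` (default 0;
#'   set above 0 to exercise pairwise deletion downstream).
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_species = 20L, n_individuals = 3L,
                              n_columns = 658L, planted_window = c(109L, 338L),
                              flank_width = 80L, rate_flank = 0.2,
                              rate_window = 3.0, rate_background = 1.0,
                              d_inter = 0.15, d_intra = 0.005, kappa = 2.0,
                              n_rate = 0) {
  stopifnot(n_species >= 2L, n_individuals >= 1L, n_columns >= 10L,
            length(planted_window) == 2L,
            planted_window[1L] >= 1L, planted_window[2L] <= n_columns,
            planted_window[1L] < planted_window[2L],
            d_intra < d_inter, rate_flank > 0, rate_window > 0,
            rate_background > 0, kappa > 0, n_rate >= 0, n_rate < 1)
  structure(
    list(n_species = as.integer(n_species),
         n_individuals = as.integer(n_individuals),
         n_columns = as.integer(n_columns),
         planted_window = as.integer(planted_window),
         flank_width = as.integer(flank_width),
         rate_flank = rate_flank, rate_window = rate_window,
         rate_background = rate_background,
         d_inter = d_inter, d_intra = d_intra, kappa = kappa,
         n_rate = n_rate),
    class = "simulation_config"
  )
}

# per-column rate multipliers for a config
.region_multipliers <- function(cfg) {
  m <- rep(cfg$rate_background, cfg$n_columns)
  pw <- cfg$planted_window
  lo <- max(1L, pw[1L] - cfg$flank_width)
  hi <- min(cfg$n_columns, pw[2L] + cfg$flank_width)
  if (lo < pw[1L]) m[lo:(pw[1L] - 1L)] <- cfg$rate_flank
  if (hi > pw[2L]) m[(pw[2L] + 1L):hi] <- cfg$rate_flank
  m[pw[1L]:pw[2L]] <- cfg$rate_window
  m
}

# expected (P, Q) fractions between two leaves joined through a common
# ancestor, each branch a single multinomial step with per-site substitution
# probability p (transition kappa/(kappa+2), transversions uniform)
.pair_pq <- function(p, kappa) {
  a <- p * kappa / (kappa + 2)   # transition
  b <- p / (kappa + 2)           # each transversion
  s <- 1 - p
  M <- matrix(b, 4L, 4L)         # order A, C, G, T
  diag(M) <- s
  M[1L, 3L] <- M[3L, 1L] <- a    # A<->G
  M[2L, 4L] <- M[4L, 2L] <- a    # C<->T
  M2 <- M %*% M
  P <- (M2[1L, 3L] + M2[3L, 1L] + M2[2L, 4L] + M2[4L, 2L]) / 4
  Q <- (sum(M2) - sum(diag(M2)) - 4 * M2[1L, 3L]) / 4
  c(P = P, Q = Q)
}

# expected overall K2P distance between two leaves when column c has per-site
# substitution probability p0 * mult[c] on each branch
.expected_k2p <- function(p0, mult, kappa) {
  um <- sort(unique(mult))
  w <- vapply(um, function(u) mean(mult == u), 0)
  pq <- vapply(um, function(u) .pair_pq(p0 * u, kappa), c(P = 0, Q = 0))
  P <- sum(w * pq["P", ]); Q <- sum(w * pq["Q", ])
  a1 <- 1 - 2 * P - Q; a2 <- 1 - 2 * Q
  if (a1 <= 0 || a2 <= 0) return(Inf)
  -0.5 * log(a1) - 0.25 * log(a2)
}

# invert the K2P expectation for the base per-site probability (bisection)
.calibrate_p <- function(target_d, mult, kappa) {
  if (target_d <= 0) return(0)
  upper <- 0.75 / max(mult)
  f <- function(p) .expected_k2p(p, mult, kappa) - target_d
  if (f(upper - 1e-9) < 0)
    stop("config error: target distance ", target_d,
         " infeasible (required substitution probability > 0.75)", call. = FALSE)
  stats::uniroot(f, c(0, upper - 1e-9), tol = 1e-6)$root
}

.mutate_seq <- function(codes, p_site, kappa) {
  hit <- which(stats::runif(length(codes)) < p_site)
  if (length(hit) == 0L) return(list(codes = codes, n_sub = 0L, n_ts = 0L))
  ts_map <- c(3L, 4L, 1L, 2L)  # A<->G, C<->T in A,C,G,T coding
  is_ts <- stats::runif(length(hit)) < kappa / (kappa + 2)
  new <- integer(length(hit))
  new[is_ts] <- ts_map[codes[hit[is_ts]]]
  if (any(!is_ts)) {
    cur <- codes[hit[!is_ts]]
    # the two transversion targets of each base
    tv_map <- matrix(c(2L, 4L,  1L, 3L,  2L, 4L,  1L, 3L), nrow = 2L)
    pick <- 1L + (stats::runif(sum(!is_ts)) < 0.5)
    new[!is_ts] <- tv_map[cbind(pick, cur)]
  }
  codes[hit] <- new
  list(codes = codes, n_sub = length(hit), n_ts = sum(is_ts))
}

#' Simulate a species-structured barcode alignment
#'
#' Draws a uniform-composition ancestral sequence, evolves one ancestor per
#' species (star phylogeny) and then each individual from its species
#' ancestor, with per-site substitution probabilities scaled by the region
#' multipliers and calibrated so the expected pairwise K2P distances match
#' `d_inter` (between species) and `d_intra` (within species). Fully
#' reproducible from the seed.
#'
#' @param cfg a `simulation_config`.
#' @param seed integer seed.
#' @return list with `alignment` (a `species_alignment`, headers
#'   `simNNN|Species_k`) and `truth` (planted window, per-column rate
#'   multipliers, species ancestor sequences, realized substitution and
#'   transition counts, calibrated per-branch probabilities, seed).
#' @export
simulate_dataset <- function(cfg = simulation_config(), seed = 1L) {
  stopifnot(inherits(cfg, "simulation_config"))
  mult <- .region_multipliers(cfg)
  p_inter <- .calibrate_p(cfg$d_inter, mult, cfg$kappa)
  p_intra <- .calibrate_p(cfg$d_intra, mult, cfg$kappa)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(as.integer(seed))
  bases <- c("A", "C", "G", "T")
  root <- sample.int(4L, cfg$n_columns, replace = TRUE)
  p_site_inter <- p_inter * mult
  p_site_intra <- p_intra * mult
  ids <- character(0); species <- character(0); seqs <- character(0)
  anc_seqs <- character(cfg$n_species)
  n_sub <- 0L; n_ts <- 0L
  idx <- 0L
  for (s in seq_len(cfg$n_species)) {
    sp_name <- sprintf("Species_%02d", s)
    anc <- .mutate_seq(root, p_site_inter, cfg$kappa)
    n_sub <- n_sub + anc$n_sub; n_ts <- n_ts + anc$n_ts
    anc_seqs[s] <- paste(bases[anc$codes], collapse = "")
    for (i in seq_len(cfg$n_individuals)) {
      idx <- idx + 1L
      ind <- .mutate_seq(anc$codes, p_site_intra, cfg$kappa)
      n_sub <- n_sub + ind$n_sub; n_ts <- n_ts + ind$n_ts
      ids <- c(ids, sprintf("sim%03d", idx))
      species <- c(species, sp_name)
      chars <- bases[ind$codes]
      if (cfg$n_rate > 0)
        chars[stats::runif(length(chars)) < cfg$n_rate] <- "N"
      seqs <- c(seqs, paste(chars, collapse = ""))
    }
  }
  aln <- species_alignment(seqs, ids, species)
  truth <- list(planted_window = cfg$planted_window,
                multipliers = mult,
                species_ancestors = stats::setNames(anc_seqs,
                                                    sprintf("Species_%02d", seq_len(cfg$n_species))),
                n_substitutions = n_sub, n_transitions = n_ts,
                p_branch_inter = p_inter, p_branch_intra = p_intra,
                seed = as.integer(seed))
  list(alignment = aln, truth = truth)
}
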