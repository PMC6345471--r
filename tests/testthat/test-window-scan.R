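# Window enumeration, scoring, candidate selection and final arbitration.

make_scan_fixture <- function(seed = 101, n_species = 6, n_ind = 2,
                              n_columns = 240, window = c(81, 160)) {
  cfg <- simulation_config(n_species = n_species, n_individuals = n_ind,
                           n_columns = n_columns, planted_window = window,
                           flank_width = 40)
  simulate_dataset(cfg, seed = seed)
}

test_that("window enumeration follows the start/step arithmetic", {
  w <- enumerate_windows(250, lengths = 230, step = 10)
  expect_equal(w$start, c(1, 11, 21))
  expect_equal(w$end, c(230, 240, 250))

  w2 <- enumerate_windows(658, lengths = 100, step = 10)
  expect_equal(nrow(w2), floor((658 - 100) / 10) + 1)
  expect_equal(nrow(w2), 56L)

  # the default grid spans 14 distinct lengths
  w3 <- enumerate_windows(658)
  expect_equal(length(unique(w3$length)), 14L)
  expect_true(all(w3$end <= 658))

  expect_error(enumerate_windows(200, lengths = 230), "exceeds")
})

test_that("a window covering the full alignment scores congruence 1 and the full-matrix mean", {
  sim <- make_scan_fixture()
  aln <- sim$alignment
  m <- k2p_matrix(aln)
  ref <- nj_tree(m, na_action = "drop")
  sc <- score_window(aln, list(start = 1, end = aln$n_columns), ref)
  expect_equal(sc$congruence, 1)
  expect_equal(sc$mean_k2p, mean(m$d[lower.tri(m$d)], na.rm = TRUE),
               tolerance = 1e-12)
})

test_that("an invariant window has zero mean distance and all-zero cells", {
  seqs <- paste0(strrep("ACGT", 10),
                 c("ACGTACGTAC", "GTCAGTCAGT", "TTGCAAGGCC", "CCATGGATCC"))
  aln <- tiny_alignment(seqs)
  ref <- nj_tree(k2p_matrix(aln), na_action = "drop")
  sc <- score_window(aln, list(start = 1, end = 40), ref, min_sites_frac = 0.1)
  expect_equal(sc$mean_k2p, 0)
  expect_equal(sc$prop_zero_cells, 1)
})

test_that("window slicing through the scan equals direct k2p on the slice", {
  sim <- make_scan_fixture(seed = 7)
  aln <- sim$alignment
  ref <- nj_tree(k2p_matrix(aln), na_action = "drop")
  set.seed(17)
  for (rep in 1:5) {
    s <- sample(1:(aln$n_columns - 99), 1)
    sc <- score_window(aln, list(start = s, end = s + 99), ref)
    sub <- slice_alignment(aln, s, s + 99)
    msub <- suppressWarnings(k2p_matrix(sub))
    expect_equal(sc$mean_k2p, mean(msub$d[lower.tri(msub$d)], na.rm = TRUE),
                 tolerance = 1e-12)
  }
})

test_that("the planted hypervariable window out-scores every disjoint window in mean K2P", {
  sim <- simulate_dataset(simulation_config(), seed = 1)
  aln <- sim$alignment
  pw <- sim$truth$planted_window
  ref <- nj_tree(k2p_matrix(aln), na_action = "drop")
  profile <- minibar:::k2p_profile(aln)
  planted <- score_window(aln, list(start = pw[1], end = pw[2]), ref,
                          profile = profile)
  wins <- enumerate_windows(aln$n_columns, lengths = pw[2] - pw[1] + 1, step = 10)
  disjoint <- wins[wins$end < pw[1] | wins$start > pw[2], ]
  for (k in seq_len(nrow(disjoint))) {
    sc <- score_window(aln, disjoint[k, ], ref, profile = profile)
    expect_lt(sc$mean_k2p, planted$mean_k2p)
  }
})

test_that("candidate selection keeps the top two per length with dominance and ties honoured", {
  # three windows of one length, strictly ordered on every criterion
  sc <- data.frame(start = c(1, 11, 21), length = 100, end = c(100, 110, 120),
                   mean_k2p = c(0.3, 0.2, 0.1),
                   prop_zero_noncon = c(0.0, 0.1, 0.2),
                   prop_zero_cells = 0,
                   congruence = c(0.9, 0.8, 0.7),
                   congruence_shallow = NA, flag = "")
  top <- select_candidates(sc)
  expect_equal(top$start, c(1, 11))
  expect_equal(top$name, c("100_a", "100_b"))

  # full tie on all criteria: smaller start takes rank "a"
  tie <- sc; tie$mean_k2p <- 0.2; tie$prop_zero_noncon <- 0.1; tie$congruence <- 0.8
  topt <- select_candidates(tie)
  expect_equal(topt$name[topt$start == 1], "100_a")

  # short supply: keep all available, with a warning
  expect_warning(kept <- select_candidates(sc[1, , drop = FALSE]), "keeping all")
  expect_equal(nrow(kept), 1L)
})

test_that("the default grid yields 28 candidates on a 658-column alignment", {
  sim <- simulate_dataset(simulation_config(), seed = 3)
  scan <- minibar_scan(sim$alignment)
  expect_equal(nrow(scan$candidates), 28L)
  expect_equal(nrow(scan$candidates),
               2L * length(unique(scan$scores$length)))
})

test_that("select_best arbitrates by K-score then RF then length then start", {
  sim <- make_scan_fixture(seed = 23)
  aln <- sim$alignment
  ref <- nj_tree(k2p_matrix(aln), na_action = "drop")
  scores <- scan_windows(aln, ref, lengths = c(80, 120), step = 40)
  cand <- select_candidates(scores)
  best <- select_best(cand, aln, ref)
  tab <- best$table
  # the table is sorted by the arbitration key and the winner is row 1
  key <- order(tab$k_score, tab$rf, -tab$length, tab$start)
  expect_equal(key[1], 1L)
  expect_equal(best$window$name, tab$name[1])
  expect_equal(best$comparison$k_score, min(tab$k_score))
  expect_true(all(tab$rank_by_kscore[1] <= tab$rank_by_kscore))
})

test_that("a window identical to the full alignment wins with k_score 0", {
  sim <- make_scan_fixture(seed = 5, n_columns = 200, window = c(61, 140))
  aln <- sim$alignment
  ref <- nj_tree(k2p_matrix(aln), na_action = "drop")
  scores <- scan_windows(aln, ref, lengths = c(100, 200), step = 100)
  cand <- select_candidates(scores, per_length = 1)
  best <- select_best(cand, aln, ref)
  expect_equal(best$window$length, 200L)
  expect_equal(best$comparison$k_score, 0, tolerance = 1e-9)
  expect_equal(best$comparison$rf, 0L)
})

test_that("the scan is deterministic for identical inputs", {
  sim <- make_scan_fixture(seed = 2)
  s1 <- minibar_scan(sim$alignment, lengths = c(80, 100), step = 20)
  s2 <- minibar_scan(sim$alignment, lengths = c(80, 100), step = 20)
  expect_identical(s1$scores, s2$scores)
  expect_identical(s1$best$window, s2$best$window)
})
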