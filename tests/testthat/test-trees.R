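# NJ construction, Robinson-Foulds and K-score.

test_that("three-taxon NJ matches the closed form", {
  d <- matrix(c(0, .2, .3, .2, 0, .4, .3, .4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(d)
  lens <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(lens[["A"]], 0.05, tolerance = 1e-12)
  expect_equal(lens[["B"]], 0.15, tolerance = 1e-12)
  expect_equal(lens[["C"]], 0.25, tolerance = 1e-12)
})

test_that("NJ recovers topology and branch lengths from additive matrices", {
  set.seed(21)
  for (rep in 1:10) {
    true <- random_tree(5)
    d <- ape::cophenetic.phylo(true)
    tr <- nj_tree(d)
    # path distances on the reconstruction reproduce the input exactly
    expect_equal(ape::cophenetic.phylo(tr)[rownames(d), colnames(d)], d,
                 tolerance = 1e-10)
    # every quartet agrees with the four-point condition on the input
    for (q in utils::combn(rownames(d), 4, simplify = FALSE)) {
      want <- quartet_from_distances(d, q)
      if (!is.na(want)) expect_equal(quartet_from_tree(tr, q), want)
    }
  }
})

test_that("an all-zero matrix yields a zero-length tree", {
  d <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  tr <- nj_tree(d)
  expect_equal(sum(tr$edge.length), 0)
})

test_that("missing cells error by default and drop rows on request", {
  d <- matrix(c(0, .1, NA, .1, 0, .2, NA, .2, 0), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  expect_error(nj_tree(d), "missing distances.*a~c")
  d4 <- rbind(cbind(d, d = c(NA, .3, .4)), d = c(NA, .3, .4, 0))
  colnames(d4) <- rownames(d4) <- letters[1:4]
  expect_warning(tr <- nj_tree(d4, na_action = "drop"), "dropped")
  expect_equal(sort(tr$tip.label), c("b", "c", "d"))
})

test_that("negative branch estimates are clamped with the pre-clamp values retained", {
  # distances engineered to force a negative NJ branch estimate
  d <- matrix(c(0, 0.01, 0.5, 0.5,
                0.01, 0, 0.01, 0.5,
                0.5, 0.01, 0, 0.01,
                0.5, 0.5, 0.01, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  tr <- nj_tree(d)
  expect_true(all(tr$edge.length >= 0))
  pre <- attr(tr, "pre_clamp_lengths")
  expect_equal(length(pre), length(tr$edge.length))
  expect_true(any(pre < 0))
})

test_that("RF distance matches hand-enumerated quartets and phangorn on random trees", {
  t5 <- random_tree(5)
  expect_equal(rf_distance(t5, t5), 0L)

  q1 <- ape::read.tree(text = "((A:1,B:1):1,C:1,D:1);")
  q2 <- ape::read.tree(text = "((A:1,C:1):1,B:1,D:1);")
  expect_equal(rf_distance(q1, q2), 2L)

  set.seed(13)
  for (rep in 1:20) {
    n <- sample(4:8, 1)
    a <- random_tree(n); b <- random_tree(n)
    expect_equal(rf_distance(a, b),
                 as.integer(phangorn::RF.dist(a, b)))
  }
  expect_error(rf_distance(random_tree(5), random_tree(6)), "leaf sets")
})

test_that("RF satisfies the metric axioms on random triples", {
  set.seed(29)
  for (rep in 1:10) {
    n <- sample(5:8, 1)
    a <- random_tree(n); b <- random_tree(n); c <- random_tree(n)
    expect_equal(rf_distance(a, b), rf_distance(b, a))
    expect_equal(rf_distance(a, a), 0L)
    expect_true(rf_distance(a, c) <= rf_distance(a, b) + rf_distance(b, c))
  }
})

test_that("K-score reproduces the worked quartet example and its identities", {
  q1 <- ape::read.tree(text = "((A:1,B:1):1,C:1,D:1);")
  q2 <- ape::read.tree(text = "((A:1,C:1):1,B:1,D:1);")
  cmp <- k_score(q1, q2)
  expect_equal(cmp$K, 0.8, tolerance = 1e-12)
  expect_equal(cmp$k_score, sqrt(1.8), tolerance = 1e-12)
  expect_equal(cmp$rf, 2L)

  # identity and exact-rescaling zeroes
  set.seed(31)
  for (rep in 1:10) {
    tr <- random_tree(sample(4:8, 1))
    self <- k_score(tr, tr)
    expect_equal(self$K, 1, tolerance = 1e-12)
    expect_equal(self$k_score, 0, tolerance = 1e-12)
    expect_equal(self$rf, 0L)
    c0 <- runif(1, 0.1, 5)
    sc <- tr; sc$edge.length <- tr$edge.length / c0
    cmp2 <- k_score(tr, sc)
    expect_equal(cmp2$K, c0, tolerance = 1e-9)
    expect_equal(cmp2$k_score, 0, tolerance = 1e-9)
  }
})

test_that("for identical topologies the K-score is the no-intercept regression RSS", {
  set.seed(37)
  for (rep in 1:10) {
    tr <- random_tree(6)
    comp <- tr
    comp$edge.length <- tr$edge.length * runif(length(tr$edge.length), 0.5, 1.5)
    cmp <- k_score(tr, comp)
    fit <- lm(tr$edge.length ~ comp$edge.length - 1)
    expect_equal(cmp$K, unname(coef(fit)), tolerance = 1e-9)
    expect_equal(cmp$k_score^2, sum(residuals(fit)^2), tolerance = 1e-9)
  }
})

test_that("an all-zero comparison tree flags K as missing", {
  tr <- random_tree(5)
  z <- tr; z$edge.length <- rep(0, length(tr$edge.length))
  cmp <- k_score(tr, z)
  expect_true(is.na(cmp$K))
  expect_equal(cmp$k_score, sqrt(sum(tr$edge.length^2)), tolerance = 1e-12)
})

test_that("clade congruence is 1 for self and counts species-level splits", {
  set.seed(41)
  tr <- random_tree(8)
  species <- setNames(rep(c("sp1", "sp2", "sp3", "sp4"), each = 2),
                      paste0("t", 1:8))
  con <- clade_congruence(tr, tr, species)
  expect_equal(con$congruence, 1)
  if (!is.na(con$shallow)) expect_equal(con$shallow, 1)
})

test_that("Newick round trip preserves topology and lengths", {
  tr <- random_tree(6)
  f <- withr::local_tempfile(fileext = ".nwk")
  write_tree_newick(tr, f)
  back <- read_tree_newick(f)
  expect_equal(rf_distance(tr, back), 0L)
  expect_equal(sort(back$edge.length), sort(tr$edge.length), tolerance = 1e-9)
})
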