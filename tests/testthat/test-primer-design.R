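# Consensus, degeneracy, Tm, primer placement and in-silico PCR.

test_that("threshold consensus follows the IUPAC coverage rule", {
  aln <- species_alignment(c("AAGA", "AAGC", "GACA", "GACT"),
                           paste0("x", 1:4), rep(c("s1", "s2"), 2))
  # col1 50/50 A,G -> R; col2 all A -> A; col3 50/50 G,C -> S; col4 ACT -> H
  expect_equal(consensus_iupac(aln, c(1, 4), freq_threshold = 0.05), "RASH")
  # the 25%-frequency bases drop out at threshold 0.3, leaving plain A
  expect_equal(consensus_iupac(aln, c(4, 4), freq_threshold = 0.3), "A")
  # rare variant below threshold is ignored (97/3 style)
  many <- species_alignment(c(rep("A", 32), "C"), paste0("x", 1:33),
                            rep("s", 33))
  expect_equal(consensus_iupac(many, c(1, 1), freq_threshold = 0.05), "A")
  # all four bases above threshold -> N
  four <- species_alignment(c("A", "C", "G", "T"), paste0("x", 1:4),
                            rep("s", 4))
  expect_equal(consensus_iupac(four, c(1, 1)), "N")
  # all-gap column -> N with warning
  gappy <- species_alignment(c("-A", "-A"), c("a", "b"), c("s", "s"))
  expect_warning(cons <- consensus_iupac(gappy, c(1, 2)), "all-gap")
  expect_equal(cons, "NA")
})

test_that("degeneracy is the product of IUPAC cardinalities", {
  expect_equal(primer_degeneracy("GGWGATGAYCAAATTTAYAAGT"), 8L)
  expect_equal(primer_degeneracy("CCWACTCCTCTTTCTACTATTCC"), 2L)
  expect_equal(primer_degeneracy("ACGT"), 1L)
  expect_equal(primer_degeneracy("NN"), 16L)
  expect_error(primer_degeneracy("ACGX"), "invalid")
})

test_that("IUPAC reverse complement is an involution consistent with base sets", {
  expect_equal(revcomp_iupac("GGWGAT"), "ATCWCC")
  set.seed(43)
  for (rep in 1:10) {
    s <- paste(sample(names(minibar:::IUPAC_CODES), 12, TRUE), collapse = "")
    expect_equal(revcomp_iupac(revcomp_iupac(s)), s)
  }
})

test_that("Wallace Tm ranges span the extreme degenerate expansions", {
  expect_equal(unname(tm_estimate("AAAA")), c(8, 8))
  expect_equal(unname(tm_estimate("GGGG")), c(16, 16))
  expect_equal(unname(tm_estimate("RRRR")), c(8, 16))
  expect_equal(unname(tm_estimate("ACGT")), c(12, 12))
})

test_that("perfectly conserved flanks give degeneracy-1 primers abutting the window", {
  set.seed(47)
  flank_l <- random_seq(40)
  flank_r <- random_seq(40)
  core <- replicate(6, random_seq(60))
  aln <- tiny_alignment(paste0(flank_l, core, flank_r))
  pair <- design_primers(aln, list(start = 41, end = 100), flank_width = 40,
                         len_range = c(18, 22))
  expect_equal(pair$degeneracy_f, 1L)
  expect_equal(pair$degeneracy_r, 1L)
  # proximity scoring pushes the placements against the window
  expect_equal(pair$fwd_span[2], 40)
  expect_equal(pair$rev_span[1], 101)
  expect_equal(pair$amplicon_span, c(pair$fwd_span[1], pair$rev_span[2]))
})

test_that("fully random flanks exceed the degeneracy cap and fail by design", {
  set.seed(53)
  seqs <- replicate(8, random_seq(140))
  aln <- tiny_alignment(seqs)
  expect_error(design_primers(aln, list(start = 51, end = 90),
                              flank_width = 50, freq_threshold = 0.05),
               "design error")
})

test_that("in-silico PCR finds constructed sites and reports the amplicon arithmetic", {
  set.seed(59)
  fwd <- random_seq(22)
  rev_site <- random_seq(23)  # sense-strand site of the reverse primer
  target <- paste0(random_seq(100), fwd, random_seq(219), rev_site,
                   random_seq(40))
  pair <- structure(list(forward = fwd, reverse = revcomp_iupac(rev_site),
                         fwd_span = c(1, 22), rev_span = c(341, 363),
                         degeneracy_f = 1L, degeneracy_r = 1L,
                         tm_range_f = tm_estimate(fwd),
                         tm_range_r = tm_estimate(rev_site),
                         amplicon_span = c(1, 363), amplicon_length = 363),
                    class = "primer_pair")
  res <- insilico_pcr(pair, data.frame(id = "t1", species = "sp",
                                       sequence = target))
  expect_true(res$success)
  expect_equal(res$fwd_mismatches, 0L)
  expect_equal(res$rev_mismatches, 0L)
  # forward site 101-122, reverse site ends at 364+... = 101+22+219+23-1
  expect_equal(res$amplicon_length, 22L + 219L + 23L)
  expect_equal(nchar(res$predicted_amplicon), res$amplicon_length)

  # a 3'-terminal mismatch in the forward site, otherwise perfect
  bad3 <- target
  pos <- 122  # last base of the forward site
  cur <- substr(bad3, pos, pos)
  substr(bad3, pos, pos) <- setdiff(c("A", "C", "G", "T"), cur)[1]
  res3 <- insilico_pcr(pair, data.frame(id = "t2", species = "sp",
                                        sequence = bad3))
  expect_false(res3$success)
  expect_equal(res3$failure_reason, "three_prime_mismatch")

  # no reverse site at all
  norev <- paste0(random_seq(100), fwd, random_seq(100))
  resn <- insilico_pcr(pair, data.frame(id = "t3", species = "sp",
                                        sequence = norev))
  expect_false(resn$success)
  expect_equal(resn$failure_reason, "no_rev_site")
})

test_that("degenerate positions match every base they encode", {
  pair <- structure(list(forward = "ACGTWACGTWACGTWACGTW",
                         reverse = revcomp_iupac("CCGGAACCGGAACCGGAACC")),
                    class = "primer_pair")
  tpl <- function(w) paste0(strrep("T", 30),
                            gsub("W", w, "ACGTWACGTWACGTWACGTW"),
                            strrep("G", 60), "CCGGAACCGGAACCGGAACC",
                            strrep("T", 30))
  for (w in c("A", "T")) {
    res <- insilico_pcr(pair, data.frame(id = w, species = "s",
                                         sequence = tpl(w)))
    expect_true(res$success)
    expect_equal(res$fwd_mismatches, 0L)
  }
})

test_that("in-silico success is monotone in the mismatch budget", {
  set.seed(61)
  fwd <- random_seq(20)
  rev_site <- random_seq(20)
  base <- paste0(random_seq(50), fwd, random_seq(150), rev_site, random_seq(50))
  pair <- structure(list(forward = fwd, reverse = revcomp_iupac(rev_site)),
                    class = "primer_pair")
  for (rep in 1:10) {
    mut <- base
    # mutate up to 3 random positions inside the primer sites (clamps excluded)
    for (k in seq_len(sample(0:3, 1))) {
      p <- sample(c(51:66, 221:236), 1)
      substr(mut, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                          substr(mut, p, p)), 1)
    }
    tgt <- data.frame(id = "t", species = "s", sequence = mut)
    succ <- vapply(0:4, function(mm)
      insilico_pcr(pair, tgt, max_mismatch = mm)$success, TRUE)
    expect_true(all(diff(succ) >= 0))  # never flips success -> failure
  }
})

test_that("designed primers on simulated data amplify every species", {
  sim <- simulate_dataset(simulation_config(), seed = 2)
  aln <- sim$alignment
  pw <- sim$truth$planted_window
  pair <- design_primers(aln, list(start = pw[1], end = pw[2]))
  res <- insilico_pcr(pair, aln)
  by_sp <- amplification_by_species(res)
  expect_true(all(by_sp$any_success))
  expect_equal(nrow(by_sp), 20L)
})
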