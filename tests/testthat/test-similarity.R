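ab_dna <- make_alphabet("DNA")
sc_dna <- scoring_scheme(ab_dna)

test_that("block matching finds shared k-mer runs", {
  s <- "ACGTACGGTACGATCAGCTAGCTA"
  i1 <- encode_kmers(s, 5, ab_dna)
  m <- match_blocks(i1, i1)
  # identical sequences: the main diagonal carries a block covering all
  # positions (internal repeats may add off-diagonal blocks)
  main <- which(m[, 1] == 0L & m[, 2] == 0L)
  expect_length(main, 1L)
  expect_identical(unname(m[main, 3]), nchar(s))
  # no shared k-mers
  i2 <- encode_kmers("ACGTACGT", 4, ab_dna)
  i3 <- encode_kmers("CCCCCCCC", 4, ab_dna)
  expect_identical(nrow(match_blocks(i2, i3)), 0L)
  # shared suffix run: blocks must contain the ACGT block found by
  # brute-force window comparison
  a <- "ACGTACGT"; b <- "TTTTACGT"
  ia <- encode_kmers(a, 4, ab_dna); ib <- encode_kmers(b, 4, ab_dna)
  m <- match_blocks(ia, ib)
  # brute force: all window pairs with equal content
  hits <- NULL
  for (i in 0:(nchar(a) - 4)) for (j in 0:(nchar(b) - 4)) {
    if (substr(a, i + 1, i + 4) == substr(b, j + 1, j + 4))
      hits <- rbind(hits, c(i, j))
  }
  for (t in seq_len(nrow(hits))) {
    covered <- any(m[, 1] <= hits[t, 1] & hits[t, 1] + 4 <= m[, 1] + m[, 3] &
                   m[, 1] - m[, 2] == hits[t, 1] - hits[t, 2])
    expect_true(covered)
  }
})

test_that("collinear chaining excludes order-inconsistent matches", {
  # region 50-100 of seq1 matches region 1-50 of seq2 (0-based: 49, 0, len 51);
  # a 5-mer matching positions 1-5 against 55-59 conflicts with that order
  cand <- rbind(c(49L, 0L, 51L), c(0L, 54L, 5L))
  ch <- chain_blocks(candidates = cand)
  expect_identical(nrow(ch$blocks), 1L)
  expect_identical(unname(ch$blocks[1, 3]), 51L)
  expect_identical(ch$anchored, 51)
  # single candidate: kept as is
  ch1 <- chain_blocks(candidates = rbind(c(3L, 8L, 6L)))
  expect_identical(ch1$anchored, 6)
  expect_identical(nrow(ch1$blocks), 1L)
})

test_that("chain total equals the exhaustive-subset oracle", {
  set.seed(99)
  for (rep in 1:120) {
    n <- sample(2:12, 1)
    blocks <- random_blocks(n)
    got <- chain_blocks(candidates = blocks)
    expect_identical(got$anchored, oracle_chain_total(blocks))
    # ordering invariant of the kept chain
    b <- got$blocks
    if (nrow(b) > 1) {
      e1 <- b[-nrow(b), 1] + b[-nrow(b), 3]
      e2 <- b[-nrow(b), 2] + b[-nrow(b), 3]
      expect_true(all(e1 <= b[-1, 1] & e2 <= b[-1, 2]))
    }
  }
})

test_that("k-mer similarity follows the anchored-positions definition", {
  # identical sequences
  s <- rand_seq(80)
  i1 <- encode_kmers(s, 5, ab_dna)
  ks <- kmer_similarity(chain_blocks(i1, i1), 80, 80)
  expect_equal(ks$similarity, 1)
  expect_equal(ks$coverage, 1)
  # empty chain
  ks0 <- kmer_similarity(matrix(integer(0), 0, 3), 80, 80)
  expect_equal(ks0$similarity, 0)
  # hand-built: anchors of 80 positions, estimated overlap 100, one
  # inter-anchor interval with unequal flanking lengths -> 80 / 101
  blocks <- rbind(c(0L, 0L, 40L), c(45L, 50L, 40L))
  ks1 <- kmer_similarity(blocks, 100, 120)
  expect_equal(ks1$similarity, 80 / 101)
})

test_that("anchored alignment matches the independent overlap-DP oracle", {
  set.seed(5)
  # empty chain = plain global alignment with free end gaps; the score
  # must equal Biostrings' overlap alignment under the same scoring
  for (rep in 1:15) {
    s1 <- rand_seq(sample(20:60, 1))
    s2 <- rand_seq(sample(20:60, 1))
    aln <- anchored_align(s1, s2, matrix(integer(0), 0, 3), sc_dna, ab_dna)
    oracle <- biostrings_overlap_score(s1, s2)
    expect_equal(aln$score, oracle, tolerance = 1e-8)
  }
  # identical sequences through their chain: perfect identity, no gaps
  s <- rand_seq(70)
  i1 <- encode_kmers(s, 5, ab_dna)
  aln <- anchored_align(s, s, chain_blocks(i1, i1), sc_dna, ab_dna)
  pid <- percent_identity(aln)
  expect_equal(pid$identity, 1)
  expect_identical(aln$gap_runs, 0L)
})

test_that("anchoring constrains but does not beat unconstrained alignment", {
  set.seed(17)
  worse <- 0
  for (rep in 1:60) {
    anc <- rand_seq(60)
    s1 <- mutate_seq(anc, 0.08)
    s2 <- mutate_seq(anc, 0.08)
    i1 <- encode_kmers(s1, 5, ab_dna)
    i2 <- encode_kmers(s2, 5, ab_dna)
    ch <- chain_blocks(i1, i2)
    a_chain <- anchored_align(s1, s2, ch, sc_dna, ab_dna)
    a_free <- anchored_align(s1, s2, matrix(integer(0), 0, 3), sc_dna, ab_dna)
    expect_lte(a_chain$score, a_free$score + 1e-9)
    id_chain <- percent_identity(a_chain)$identity
    id_free <- percent_identity(a_free)$identity
    # identity ratios can differ slightly when anchoring trades gap runs
    # for mismatches; the anchored identity must not beat the
    # unconstrained identity beyond a small tolerance
    if (id_chain > id_free + 0.05) worse <- worse + 1
  }
  expect_lte(worse, 3)
})

test_that("percent identity respects the gap-mode definitions", {
  # toy alignment ACGT-A / ACGTTA: 5 matches, one single-position gap run
  counts <- list(matches = 5L, mismatches = 0L, gap_runs = 1L,
                 gap_positions = 1L, overlap_length = 6L,
                 len1 = 5L, len2 = 6L)
  expect_equal(percent_identity(counts, sim_config())$identity, 5 / 6)
  expect_equal(percent_identity(counts,
                 sim_config(gap_mode = "ignore"))$identity, 1)
  expect_equal(percent_identity(counts,
                 sim_config(gap_mode = "per-position-mismatch"))$identity, 5 / 6)
  # all-mismatch overlap
  bad <- list(matches = 0L, mismatches = 8L, gap_runs = 0L,
              gap_positions = 0L, overlap_length = 8L, len1 = 8L, len2 = 8L)
  expect_equal(percent_identity(bad)$identity, 0)
  # zero-length overlap
  none <- list(matches = 0L, mismatches = 0L, gap_runs = 0L,
               gap_positions = 0L, overlap_length = 0L, len1 = 5L, len2 = 5L)
  out <- percent_identity(none)
  expect_equal(out$identity, 0)
  expect_false(out$pass)
})

test_that("similarity is symmetric under sequence swap", {
  set.seed(23)
  for (rep in 1:20) {
    anc <- rand_seq(90)
    s1 <- mutate_seq(anc, 0.1)
    s2 <- mutate_seq(anc, 0.1)
    p12 <- pair_similarity(s1, s2, k = 5, alphabet = ab_dna)
    p21 <- pair_similarity(s2, s1, k = 5, alphabet = ab_dna)
    expect_equal(p12$kmer_similarity, p21$kmer_similarity, tolerance = 1e-12)
    expect_equal(p12$identity, p21$identity, tolerance = 1e-12)
  }
})

test_that("k-mer similarity bounds aligned identity on homologous pairs", {
  set.seed(31)
  n <- 200
  viol <- 0
  for (rep in seq_len(n)) {
    anc <- rand_seq(sample(100:250, 1))
    r1 <- runif(1, 0.01, 0.12)
    s1 <- mutate_seq(anc, r1)
    s2 <- mutate_seq(anc, r1)
    ps <- pair_similarity(s1, s2, alphabet = ab_dna)
    if (ps$kmer_similarity > ps$identity + 1e-9) viol <- viol + 1
  }
  expect_lte(viol / n, 0.05)
})

test_that("scoring schemes are symmetric and read from NCBI-format files", {
  expect_true(isSymmetric(unname(sc_dna$substitution)))
  expect_identical(sc_dna$substitution["A", "G"], 0)   # transition
  expect_identical(sc_dna$substitution["A", "C"], -3)  # transversion
  sc_aa <- scoring_scheme(make_alphabet("AA"))
  expect_true(isSymmetric(unname(sc_aa$substitution)))
  # round-trip through the square matrix text format
  f <- tempfile(fileext = ".mat")
  m <- sc_dna$substitution
  write.table(m, f, quote = FALSE)
  m2 <- read_score_matrix(f)
  expect_equal(m2, m)
})
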