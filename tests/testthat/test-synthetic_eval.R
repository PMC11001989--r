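test_that("the family generator is seeded, labeled and rate-faithful", {
  # zero divergence: all members identical to the ancestor
  fam0 <- generate_families(2, 4, 100, substitution_rate = 0,
                            indel_rate = 0, seed = 1)
  for (f in c("F001", "F002")) {
    m <- fam0$sequences[fam0$labels$family == f]
    expect_identical(length(unique(m)), 1L)
  }
  # single sequence
  fam1 <- generate_families(1, 1, 50, seed = 2)
  expect_length(fam1$sequences, 1L)
  # byte-identical under the same seed
  a <- generate_families(3, 5, 120, seed = 9)
  b <- generate_families(3, 5, 120, seed = 9)
  expect_identical(a$sequences, b$sequences)
  expect_identical(a$labels, b$labels)
  # substitution rate 0.05, no indels, length 1000: mean member-ancestor
  # identity ~ 0.95 within 3 standard errors (binomial expectation)
  fam <- generate_families(1, 100, 1000, substitution_rate = 0.05,
                           indel_rate = 0, seed = 3)
  anc <- strsplit(fam$ancestors[["F001"]], "")[[1]]
  ids <- vapply(seq_len(100), function(i) {
    m <- strsplit(fam$sequences[[i]], "")[[1]]
    mean(m == anc)
  }, 0)
  se <- sd(ids) / sqrt(length(ids))
  expect_lt(abs(mean(ids) - 0.95), 3 * se)
  # contradictory specs error out
  expect_error(generate_families(2, 2, 50, substitution_rate = 1))
  expect_error(generate_families(2, 2, 50, root_divergence = 1.5))
  # truncation produces partial-length members
  famt <- generate_families(2, 20, 200, truncate_frac = 0.5, seed = 4)
  expect_true(any(nchar(famt$sequences) < 150))
})

test_that("label consistency follows the size-minus-one weighting", {
  expect_equal(label_consistency(c(1, 1, 2, 2), c("a", "a", "b", "b")), 1)
  # sizes (3, 1), modal fractions (2/3, 1): (2/3*2 + 1*0) / 2 = 2/3
  expect_equal(label_consistency(c(1, 1, 1, 2), c("a", "a", "b", "c")), 2 / 3)
  # one pair with distinct labels
  expect_equal(label_consistency(c(1, 1), c("a", "b")), 1 / 2)
  # all singletons are vacuously consistent
  expect_equal(label_consistency(1:4, c("a", "a", "b", "b")), 1)
  # invariance under relabeling of clusters and permutation of labels
  cl <- c(1, 1, 1, 2, 2, 3)
  lb <- c("a", "a", "b", "b", "b", "c")
  expect_equal(label_consistency(cl, lb),
               label_consistency(c(9, 9, 9, 4, 4, 7)[rank(cl)], lb))
})

test_that("violation rate counts within-cluster pairs below threshold", {
  # duplicate-only clusters never violate
  s <- rand_seq(80)
  out <- violation_rate(c(1, 1, 1), c(s, s, s), threshold = 1)
  expect_equal(out$rate, 0)
  expect_true(out$defined)
  # a single cluster of three enumerates all three pairs
  set.seed(6)
  expect_identical(out$n_pairs, 3L)
  # constructed cluster {rep, a, b}: a and b match rep at ~0.93 but each
  # other below 0.9; at threshold 0.9 exactly one of three pairs violates.
  # The differing positions sit in the interior so they stay inside the
  # overlap region (terminal mismatches can be absorbed into free end gaps)
  set.seed(1)
  base <- rand_seq(120)
  ch <- strsplit(base, "")[[1]]
  flip <- function(x) c(A = "C", C = "G", G = "T", T = "A")[[x]]
  a <- ch; for (i in 40:48) a[i] <- flip(a[i])
  b <- ch; for (i in 52:60) b[i] <- flip(b[i])
  sq <- c(base, paste(a, collapse = ""), paste(b, collapse = ""))
  # confirm the designed identities through the package's own measure
  expect_gte(pair_similarity(sq[1], sq[2])$identity, 0.9)
  expect_gte(pair_similarity(sq[1], sq[3])$identity, 0.9)
  expect_lt(pair_similarity(sq[2], sq[3])$identity, 0.9)
  out2 <- violation_rate(c(1, 1, 1), sq, threshold = 0.9)
  expect_equal(out2$rate, 1 / 3)
  # no eligible pairs
  out3 <- violation_rate(1:3, c(s, s, s), threshold = 0.9)
  expect_false(out3$defined)
})

test_that("violation sampling agrees with exhaustive enumeration", {
  set.seed(8)
  fam <- generate_families(3, 8, 120, substitution_rate = 0.06, seed = 12)
  cl <- as.integer(factor(fam$labels$family))
  full <- violation_rate(cl, fam$sequences, 0.9, max_pairs = 10000)
  samp <- violation_rate(cl, fam$sequences, 0.9, max_pairs = 40)
  se <- sqrt(full$rate * (1 - full$rate) / 40) + 1e-6
  expect_lt(abs(samp$rate - full$rate), 4 * se + 0.05)
})

test_that("mutual information scores match an independent implementation", {
  # perfect agreement
  mi <- mutual_information_scores(c(1, 1, 2, 2, 3), c("x", "x", "y", "y", "z"))
  expect_equal(mi$nmi, 1)
  expect_equal(mi$ami, 1)
  # one cluster vs balanced labels carries no information
  mi0 <- mutual_information_scores(rep(1, 10), rep(c("a", "b"), 5))
  expect_equal(mi0$nmi, 0)
  expect_equal(mi0$ami, 0)
  # 3x3 contingency fixture, reference values frozen from scikit-learn's
  # arithmetic-mean normalization and hypergeometric expected MI
  clusters <- rep(c(1, 1, 2, 2, 3, 3), c(5, 2, 3, 6, 1, 4))
  labels <- rep(c("a", "b", "a", "c", "b", "c"), c(5, 2, 3, 6, 1, 4))
  mi3 <- mutual_information_scores(clusters, labels)
  expect_equal(mi3$nmi, 0.3938069, tolerance = 1e-6)
  expect_equal(mi3$ami, 0.3152599, tolerance = 1e-6)
  # ami <= nmi <= 1
  expect_lte(mi3$ami, mi3$nmi)
  # degenerate: single cluster, single label
  mi1 <- mutual_information_scores(rep(1, 4), rep("a", 4))
  expect_equal(mi1$nmi, 1)
})

test_that("the scaling exponent is the top-four log-log slope", {
  expect_equal(scaling_exponent(c(1e3, 2e3, 4e3, 8e3), c(1, 2, 4, 8)), 1)
  expect_equal(scaling_exponent(c(1e3, 2e3, 4e3, 8e3), c(1, 4, 16, 64)), 2)
  # only the largest four sizes enter the fit
  expect_equal(scaling_exponent(c(10, 1e3, 2e3, 4e3, 8e3),
                                c(999, 1, 2, 4, 8)), 1)
  # noisy power law recovered within tolerance
  set.seed(10)
  sizes <- c(5e3, 1e4, 2e4, 4e4)
  reps <- vapply(1:20, function(r) {
    times <- sizes^1.3 * exp(rnorm(4, sd = 0.05))
    scaling_exponent(sizes, times)
  }, 0)
  expect_lt(abs(mean(reps) - 1.3), 0.1)
  expect_error(scaling_exponent(c(-1, 2, 3, 4), c(1, 2, 3, 4)))
  expect_error(scaling_exponent(c(1, 2, 3), c(1, 2, 3)))
})
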