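test_that("reference picks follow their stated probability weights", {
  # single-member group
  expect_identical(pick_first(0, 100), 1L)
  # p proportional to v * L: (2000,2000) x (100,300) -> (0.25, 0.75)
  set.seed(61)
  draws <- replicate(2e4, pick_first(c(2000, 2000), c(100, 300)))
  p_hat <- mean(draws == 2L)
  se <- sqrt(0.75 * 0.25 / 2e4)
  expect_lt(abs(p_hat - 0.75), 3 * se)
  # all-zero weights fall back to uniform
  draws0 <- replicate(5e3, pick_first(c(0, 0), c(10, 10)))
  expect_lt(abs(mean(draws0 == 1L) - 0.5), 3 * sqrt(0.25 / 5e3))
  # second pick: d1/(dov+1): (0.4, 0.4) x (0, 1) -> (2/3, 1/3)
  draws2 <- replicate(2e4, pick_second(c(0.4, 0.4), c(0, 1)))
  expect_lt(abs(mean(draws2 == 1L) - 2 / 3), 3 * sqrt(2 / 9 / 2e4))
  # zero-distance sequences are never selected
  draws3 <- replicate(200, pick_second(c(0, 0.5, 0.2), c(0, 0, 0)))
  expect_false(any(draws3 == 1L))
})

test_that("relative distances are antisymmetric differences", {
  d1 <- c(0.2, 0.5, 0.8)
  d2 <- c(0.2, 0.3, 0.9)
  expect_equal(relative_distances(d1, d2), d1 - d2)
  expect_equal(relative_distances(d1, d1), rep(0, 3))      # equidistant
  expect_equal(relative_distances(d2, d1), -(d1 - d2))     # swap negates
  expect_equal(relative_distances(0, 0.8), -0.8)           # at first pick
})

test_that("projection equals the leading principal component", {
  set.seed(71)
  for (rep in 1:50) {
    d_prev <- rnorm(50)
    d_new <- 0.6 * d_prev + rnorm(50, sd = runif(1, 0.1, 2))
    got <- project_distances(d_prev, d_new)
    pc1 <- prcomp(cbind(d_prev, d_new), center = TRUE)$x[, 1]
    expect_gt(abs(cor(got, pc1)), 1 - 1e-8)
    # sign convention: nonnegative correlation with the previous vector
    expect_gte(cor(got, d_prev), 0)
  }
  # degenerate inputs
  d <- c(1, 2, 3)
  expect_equal(project_distances(d, d - mean(d)),
               project_distances(d, d - mean(d)))
  # uninformative previous vector: rank order of the new vector prevails
  got <- project_distances(rep(0, 4), c(3, 1, 4, 2))
  expect_identical(order(got), order(c(3, 1, 4, 2)))
  # both constant: previous kept
  expect_identical(project_distances(rep(1, 4), rep(2, 4)), rep(1, 4))
})

test_that("rank movement updates use the capped moving average", {
  # no movement from v = 2000: 0.05*0 + 0.95*2000 = 1900
  up <- update_rank_and_v(c(1, 2, 3), 1:3, rep(2000, 3))
  expect_equal(up$v, rep(1900, 3))
  # stable fixed point at zero
  up0 <- update_rank_and_v(c(1, 2, 3), 1:3, rep(0, 3))
  expect_equal(up0$v, rep(0, 3))
  # movement beyond the cap contributes only the cap
  n <- 30
  up2 <- update_rank_and_v(seq_len(n), rev(seq_len(n)), rep(0, n),
                           alpha = 1, cap = 10)
  expect_true(all(up2$v <= 10))
  expect_equal(max(up2$v), 10)
  # order output is a permutation
  set.seed(4)
  D <- rnorm(40)
  up3 <- update_rank_and_v(D, sample(40), runif(40, 0, 2000))
  expect_setequal(up3$order, 1:40)
  expect_true(all(up3$v <= 2000))
})

test_that("group splitting respects the minimum group size", {
  # one stabilized sequence at rank 1500 of 3000: both sides < 2000
  v <- rep(1500, 3000); v[1500] <- 500
  expect_length(split_groups(v, 2000, 1000), 0L)
  # stabilized at rank 2500 of 5000: split into 2500 + 2500
  v2 <- rep(1500, 5000); v2[2500] <- 500
  expect_identical(split_groups(v2, 2000, 1000), 2500L)
  # a group smaller than twice the minimum never splits
  v3 <- rep(0, 3999)
  expect_length(split_groups(v3, 2000, 1000), 0L)
})

test_that("relatedness sorting is deterministic and separates families", {
  fam <- generate_families(2, 100, 200, seed = 19)
  pl <- build_rare_pipeline(fam$sequences)
  ab <- make_alphabet("DNA")
  codes <- relclust:::encode_sequences(fam$sequences, ab)
  k <- pl$plan$k_match
  kidx <- lapply(codes, function(cv) relclust:::encode_kmers_cpp(cv, k, 4L))
  seqdata <- list(kmers = lapply(kidx, `[[`, "kmers"),
                  positions = lapply(kidx, `[[`, "positions"))
  lens <- nchar(fam$sequences)
  # interleave the two families, then sort the whole set as one partition
  members <- as.integer(rbind(which(fam$labels$family == "F001"),
                              which(fam$labels$family == "F002")))
  ok_runs <- 0L
  for (sd in 1:10) {
    set.seed(sd)
    ph <- run_phase2(members, seqdata, lens, k, clust_params())
    runs <- rle(fam$labels$family[ph$order])
    if (length(runs$lengths) <= 4) ok_runs <- ok_runs + 1L
  }
  expect_gte(ok_runs, 9L)
  # determinism: same seed, same final order
  set.seed(123); o1 <- run_phase2(members, seqdata, lens, k, clust_params())
  set.seed(123); o2 <- run_phase2(members, seqdata, lens, k, clust_params())
  expect_identical(o1$order, o2$order)
  # single-sequence partition passes through untouched
  expect_identical(run_phase2(5L, seqdata, lens, k)$order, 5L)
})

test_that("sorting moves family members closer together in rank", {
  # paired comparison over seeded replicates: mean rank distance between
  # same-family pairs after sorting vs the shuffled input order
  before <- numeric(0)
  after <- numeric(0)
  for (sd in 1:20) {
    fam <- generate_families(4, 25, 150, seed = 300 + sd)
    pl <- build_rare_pipeline(fam$sequences)
    ab <- make_alphabet("DNA")
    codes <- relclust:::encode_sequences(fam$sequences, ab)
    k <- pl$plan$k_match
    kidx <- lapply(codes, function(cv) relclust:::encode_kmers_cpp(cv, k, 4L))
    seqdata <- list(kmers = lapply(kidx, `[[`, "kmers"),
                    positions = lapply(kidx, `[[`, "positions"))
    lens <- nchar(fam$sequences)
    set.seed(sd)
    members <- sample(100L)
    ph <- run_phase2(members, seqdata, lens, k, clust_params())
    rank_dist <- function(ord) {
      pos <- integer(100); pos[ord] <- seq_len(100)
      fams <- split(seq_len(100), fam$labels$family)
      mean(vapply(fams, function(m) {
        pr <- combn(pos[m], 2)
        mean(abs(pr[1, ] - pr[2, ]))
      }, 0))
    }
    before <- c(before, rank_dist(members))
    after <- c(after, rank_dist(ph$order))
  }
  expect_lt(t.test(after, before, paired = TRUE,
                   alternative = "less")$p.value, 0.01)
})

test_that("identity calibration is monotone with a conservative fallback", {
  # separable training data: passes at >= 0.8, failures below 0.5
  set.seed(41)
  ksim <- c(runif(150, 0.8, 1), runif(150, 0.05, 0.5))
  pass <- ksim >= 0.8
  cal <- calibrate_identity(ksim, pass, threshold = 0.9)
  expect_false(cal$fallback)
  expect_gt(cal$slope, 0)
  expect_gt(cal$boundary, 0.5)
  expect_lt(cal$boundary, 0.8)
  pr <- predict(cal, c(0.2, 0.6, 0.95))
  expect_true(all(diff(pr) > 0))  # monotone nondecreasing
  # one-class data: admit-all fallback
  cal1 <- calibrate_identity(runif(100, 0.7, 1), rep(TRUE, 100), 0.9)
  expect_true(cal1$fallback)
  expect_equal(predict(cal1, c(0, 0.5, 1)), rep(1, 3))
  # parameter recovery from a known logistic curve
  set.seed(42)
  b0 <- -12; b1 <- 20
  x <- runif(5000, 0.2, 1)
  y <- runif(5000) < plogis(b0 + b1 * x)
  cal2 <- calibrate_identity(x, y, 0.9, lambda = 1e-4)
  expect_lt(abs(cal2$intercept - b0) / abs(b0), 0.1)
  expect_lt(abs(cal2$slope - b1) / b1, 0.1)
})
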