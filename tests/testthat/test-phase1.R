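test_that("candidate gathering follows the ascending-group-size stopping rule", {
  # no groups of size > 1: empty candidate set
  tb <- build_rare_table(list(c(1L), c(2L), c(3L)))
  g <- gather_candidates(1, tb)
  expect_length(g$ids, 0L)
  # two identical selections: each lists the other at full count
  tb2 <- build_rare_table(list(c(1L, 5L, 9L), c(1L, 5L, 9L)))
  g2 <- gather_candidates(1, tb2)
  expect_identical(g2$ids, 2L)
  expect_identical(g2$counts, 3L)
  # 6-sequence fixture with a small candidate limit: compare against a
  # brute-force enumeration applying the same stopping rule
  selections <- list(c(0L, 1L, 2L), c(0L, 1L), c(1L, 2L), c(0L, 3L),
                     c(3L), c(2L, 3L))
  tb3 <- build_rare_table(selections)
  A <- 4
  for (focal in 1:6) {
    g3 <- gather_candidates(focal, tb3, A)
    # oracle: visit this sequence's bins by ascending group size, record
    # members until A recorded, count occurrences
    inv <- oracle_inverted_index(selections)
    bins <- selections[[focal]]
    sizes <- lengths(inv[as.character(bins)])
    o <- order(sizes)
    rec <- integer(0)
    total <- 0
    for (b in bins[o]) {
      if (total >= A) break
      rec <- c(rec, inv[[as.character(b)]])
      total <- total + length(inv[[as.character(b)]])
    }
    rec <- rec[rec != focal]
    exp_counts <- table(rec)
    expect_setequal(g3$ids, as.integer(names(exp_counts)))
    expect_identical(g3$counts[order(g3$ids)],
                     as.integer(exp_counts[order(as.integer(names(exp_counts)))]))
  }
})

test_that("background decay fit recovers geometric fall-offs", {
  # exact halving: slope is -log(2) per unit
  f <- fit_background(c(100, 50, 25, 12.5, 6.25))
  expect_false(f$degenerate)
  expect_equal(f$slope, -log(2), tolerance = 1e-9)
  # a single nonzero entry cannot be fitted
  expect_true(fit_background(c(0, 4, 0, 0))$degenerate)
  expect_true(fit_background(numeric(0))$degenerate)
  # fall-off ends at the first empty count: indices 1-5 only
  f2 <- fit_background(c(80, 40, 20, 10, 5, 0, 0, 3))
  expect_identical(f2$fit_range, c(1L, 5L))
  # extrapolation below one count is the informative regime
  expect_lt(background_expectation(f2, 12), 1)
})

test_that("homology probability converts expected background counts", {
  # geometric histogram whose extrapolation at 11 shared k-mers is 0.05
  e_at <- function(c) 0.05 * 2^(11 - c)
  hist <- e_at(1:10)
  f <- fit_background(hist)
  expect_equal(background_expectation(f, 11), 0.05, tolerance = 1e-9)
  expect_equal(homology_probability(f, 11), 0.95, tolerance = 1e-9)
  # probability floors at zero when the background expects >= 1 sequence
  expect_equal(homology_probability(f, 5), 0)
})

test_that("cumulative-product correction declares candidates in order", {
  # fit with e(12) = 0.05 and e(11) = 0.1 -> probabilities 0.95 and 0.9;
  # corrected: 0.95, then 0.95*0.9 = 0.855 < 0.9
  slope <- log(0.05 / 0.1)
  intercept <- log(0.05) - slope * 12
  fit <- structure(list(slope = slope, intercept = intercept,
                        fit_range = c(1L, 5L), bg_end = 5L,
                        saturated = FALSE, degenerate = FALSE),
                   class = "decay_fit")
  hom <- homology_probabilities(c(101L, 102L), c(12L, 11L), fit,
                                threshold = 0.9, max_possible = 50L)
  expect_identical(hom, 101L)
  # e >= 1 gives probability zero: nothing declared
  fit0 <- structure(list(slope = 0, intercept = log(2),
                         fit_range = c(1L, 2L), bg_end = 2L,
                         saturated = FALSE, degenerate = FALSE),
                    class = "decay_fit")
  expect_length(homology_probabilities(7L, 30L, fit0, 0.9, 50L), 0L)
  # degenerate fallback: half the maximum possible count
  fitd <- structure(list(degenerate = TRUE), class = "decay_fit")
  hom2 <- homology_probabilities(c(1L, 2L, 3L), c(30L, 24L, 5L), fitd,
                                 0.9, 50L)
  expect_identical(hom2, c(1L))
  hom3 <- homology_probabilities(c(1L, 2L), c(25L, 26L), fitd, 0.9, 50L)
  expect_setequal(hom3, c(1L, 2L))
})

test_that("partitions equal the connected components of declared homology", {
  set.seed(12)
  fam <- generate_families(n_families = 6, members = 5,
                           ancestor_length = 200, seed = 81)
  pl <- build_rare_pipeline(fam$sequences)
  part <- partition_sequences(pl$table)
  expect_identical(sort(unique(part$partition)),
                   seq_along(part$sizes))
  # independent route: collect declared edges, take igraph components
  n <- pl$table$n
  n_rare <- lengths(pl$selections)
  edges <- NULL
  for (i in seq_len(n)) {
    g <- gather_candidates(i, pl$table, 20000)
    if (length(g$ids) == 0L) next
    f <- fit_background(g$hist)
    hom <- homology_probabilities(g$ids, g$counts, f, 0.9, n_rare[i])
    if (length(hom) > 0L) edges <- rbind(edges, cbind(i, hom))
  }
  gr <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (!is.null(edges)) gr <- igraph::add_edges(gr, t(edges))
  comp <- unname(igraph::components(gr)$membership)
  # same partition <=> same component, for every pair
  expect_identical(outer(part$partition, part$partition, "=="),
                   outer(comp, comp, "=="))
})

test_that("high sharers are declared homologous and low sharers are not", {
  # Candidate-count mixtures with an exponentially decaying background
  # (the regime the rare-k-mer length formula establishes: unrelated
  # sequences share very few rare k-mers) plus a homologous group at
  # high shared counts. Candidates sharing more than 20 of 50 must be
  # declared; candidates sharing fewer than 10 must not (5% tolerance).
  set.seed(3)
  checked_high <- 0L; miss_high <- 0L
  low_declared <- 0L; declared_total <- 0L
  for (rep in 1:50) {
    bg <- rgeom(2000, prob = runif(1, 0.4, 0.7)) + 1L   # background counts
    bg <- bg[bg <= 15]
    fam <- sample(25:48, sample(10:60, 1), replace = TRUE)  # homologous
    counts <- c(bg, fam)
    ids <- seq_along(counts)
    hist <- tabulate(counts, nbins = max(counts))
    f <- fit_background(hist)
    hom <- homology_probabilities(ids, counts, f, 0.9, max_possible = 50L)
    high <- ids[counts > 20]
    checked_high <- checked_high + length(high)
    miss_high <- miss_high + sum(!(high %in% hom))
    declared_total <- declared_total + length(hom)
    low_declared <- low_declared + sum(counts[hom] < 10)
  }
  expect_gt(checked_high, 500L)
  expect_lte(miss_high / checked_high, 0.05)
  expect_lte(low_declared / max(1L, declared_total), 0.05)
})

test_that("families neither merge nor split across partitions", {
  # 10 families of 50, mutually unrelated ancestors, ~4% within-family
  # divergence; the co-partition property must hold in >= 95% of runs
  runs <- 20
  merge_runs <- 0L
  split_runs <- 0L
  for (sd in seq_len(runs)) {
    fam <- generate_families(10, 50, 300, seed = 7000 + sd)
    pl <- build_rare_pipeline(fam$sequences)
    part <- partition_sequences(pl$table)
    tab <- table(part$partition, fam$labels$family)
    if (any(rowSums(tab > 0) > 1)) merge_runs <- merge_runs + 1L
    if (any(colSums(tab > 0) > 1)) split_runs <- split_runs + 1L
  }
  expect_gte((runs - merge_runs) / runs, 0.95)
  expect_gte((runs - split_runs) / runs, 0.95)
})
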