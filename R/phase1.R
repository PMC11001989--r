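#' Global algorithm parameters
#'
#' Bundles the bounding constants of the three clustering phases. `A` caps
#' how many candidate sequences are gathered per focal sequence from rare
#' k-mer groups, `B` caps relatedness-sorting iterations per group, `C`
#' caps both the number of cluster representatives screened per sequence
#' and the rank-movement scale, and `E` caps the number of alignments per
#' sequence. The stability bound for relatedness sorting is `C/2`.
#'
#' @param A Candidate limit for rare-k-mer gathering (default 20000).
#' @param B Iteration limit for relatedness sorting (default 2000).
#' @param C Comparison limit / movement cap (default 2000).
#' @param E Alignment limit (default 200).
#' @param rare_per_seq Rare k-mers per sequence (default 50).
#' @param homology_prob Corrected-probability threshold for declaring
#'   homology in phase 1 (default 0.9).
#' @param alpha Smoothing parameter of the rank-movement moving average
#'   (default 0.05).
#' @param min_group Minimum group size produced by splitting during
#'   relatedness sorting (default 2000).
#' @param align_prob_floor Minimum predicted probability of meeting the
#'   similarity threshold for a candidate to be aligned (default 0.01).
#' @param calibration_pairs Number of sequence pairs aligned to calibrate
#'   the k-mer-similarity to identity model (default 1000).
#' @return A list of class `clust_params` (includes the derived
#'   `stability_bound = C/2`).
#' @export
clust_params <- function(A = 20000L, B = 2000L, C = 2000L, E = 200L,
                         rare_per_seq = 50L, homology_prob = 0.9,
                         alpha = 0.05, min_group = 2000L,
                         align_prob_floor = 0.01,
                         calibration_pairs = 1000L) {
  stopifnot(A >= 1, B >= 1, C >= 2, E >= 1, rare_per_seq >= 1,
            homology_prob > 0, homology_prob <= 1,
            alpha > 0, alpha < 1, min_group >= 1,
            align_prob_floor >= 0, align_prob_floor <= 1,
            calibration_pairs >= 1)
  structure(list(A = as.integer(A), B = as.integer(B), C = as.integer(C),
                 E = as.integer(E), rare_per_seq = as.integer(rare_per_seq),
                 homology_prob = homology_prob, alpha = alpha,
                 min_group = as.integer(min_group),
                 stability_bound = C / 2,
                 align_prob_floor = align_prob_floor,
                 calibration_pairs = as.integer(calibration_pairs)),
            class = "clust_params")
}

#' Gather candidate sequences sharing rare k-mers with a focal sequence
#'
#' Visits the focal sequence's rare-k-mer groups in ascending group size,
#' recording all member sequences of each group until the running total of
#' recorded sequences reaches `A`, and tabulates how many rare k-mers each
#' recorded sequence shares with the focal sequence. The focal sequence
#' itself is excluded.
#'
#' @param i Focal sequence index (1-based).
#' @param table A [build_rare_table()] object.
#' @param A Candidate limit.
#' @return A list with candidate `ids`, per-candidate shared `counts`, and
#'   `hist` (element c = number of candidates sharing exactly c rare
#'   k-mers).
#' @export
gather_candidates <- function(i, table, A = 20000L) {
  from <- table$seq_ptr[i] + 1L
  to <- table$seq_ptr[i + 1L]
  if (to < from)
    return(list(ids = integer(0), counts = integer(0), hist = integer(0)))
  idx <- from:to
  gather_counts_cpp(table$member, table$slot_start[idx],
                    table$slot_end[idx], i, as.numeric(A))
}

#' Fit the background decay of shared rare-k-mer counts
#'
#' Unrelated sequences share few rare k-mers, producing an initial
#' exponential fall-off in the shared-count histogram. A least-squares line
#' is fitted in log-count space over the fall-off from the histogram's
#' dominant (background) maximum to the first empty count, which marks
#' the end of the contiguous background distribution. Ties at the maximum
#' break toward the lower index. With fewer than two usable points the
#' fit is flagged degenerate and callers fall back to the
#' fraction-of-maximum rule (see [homology_probabilities()]).
#'
#' @param hist Numeric vector: element c = number of candidates sharing
#'   exactly c rare k-mers.
#' @return A list of class `decay_fit` with `slope`, `intercept`,
#'   `fit_range` and `degenerate`.
#' @export
fit_background <- function(hist) {
  counts <- as.numeric(hist)
  L <- length(counts)
  degenerate <- structure(list(slope = NA_real_, intercept = NA_real_,
                               fit_range = c(NA_integer_, NA_integer_),
                               degenerate = TRUE),
                          class = "decay_fit")
  if (L < 2L) return(degenerate)
  # start of the background fall-off: the histogram's dominant maximum
  # (ties broken toward the lower index). Using the first *local* maximum
  # is hijacked by stray counts of 1 at small shared numbers whenever the
  # hash space is small enough that unrelated sequences share several
  # rare k-mers, so the global mode is used instead.
  m <- which.max(counts)
  if (counts[m] <= 0) return(degenerate)
  # fall-off range: from the mode to the first empty count (the end of the
  # contiguous background distribution). Demanding strict monotonicity
  # truncates the fit to a couple of noisy points on real histograms, so
  # the aggregate decreasing stretch is used.
  e <- m
  while (e < L && counts[e + 1L] > 0) e <- e + 1L
  idx <- m:e
  if (length(idx) < 2L) return(degenerate)
  xs <- idx
  ys <- log(counts[idx])
  xbar <- mean(xs)
  ybar <- mean(ys)
  slope <- sum((xs - xbar) * (ys - ybar)) / sum((xs - xbar)^2)
  intercept <- ybar - slope * xbar
  # observed end of the background: stray positive counts separated from
  # the contiguous fall-off by fewer than 3 empty counts still belong to
  # the background's tail; the fitted line is extrapolation-only beyond
  # this point and candidates inside it are never declared homologous
  bg <- e
  j <- e + 1L
  gap <- 0L
  while (j <= L && gap < 3L) {
    if (counts[j] > 0) {
      bg <- j
      gap <- 0L
    } else {
      gap <- gap + 1L
    }
    j <- j + 1L
  }
  structure(list(slope = slope, intercept = intercept,
                 fit_range = c(m, e), bg_end = bg,
                 saturated = bg >= L, degenerate = FALSE),
            class = "decay_fit")
}

#' Expected background count at a shared-k-mer count
#'
#' Extrapolates the fitted decay line (without clamping; values below 1
#' are the informative regime).
#'
#' @param fit A [fit_background()] object.
#' @param count Shared rare-k-mer count(s).
#' @return Expected number of sequences sharing `count` rare k-mers by
#'   chance.
#' @export
background_expectation <- function(fit, count) {
  stopifnot(inherits(fit, "decay_fit"))
  if (fit$degenerate) return(rep(NA_real_, length(count)))
  exp(fit$intercept + fit$slope * count)
}

#' Per-count homology probability before multiple-testing correction
#'
#' The probability that a candidate sharing `count` rare k-mers is
#' homologous is one minus the expected background count at that level,
#' floored at zero. For example an expected background of 0.05 sequences
#' at 11 shared rare k-mers gives probability 0.95.
#'
#' @inheritParams background_expectation
#' @return Probabilities in `[0, 1]`.
#' @export
homology_probability <- function(fit, count) {
  pmax(0, 1 - background_expectation(fit, count))
}

#' Declare homologous candidates with cumulative-product correction
#'
#' Candidates are sorted by descending shared count (highest probability
#' first) and the running cumulative product of their per-count
#' probabilities is taken as a multiple-testing correction; a candidate is
#' declared homologous when its corrected probability is at least
#' `threshold`. Candidates whose counts lie inside the observed background
#' range (`fit$bg_end`) receive probability zero: the fitted decay is
#' extrapolation-only beyond the counts actually observed by chance. When the background fit is degenerate, candidates sharing
#' at least 50% of the maximum possible shared count are declared
#' homologous instead (mirroring the empirical behavior that sequences
#' sharing more than 20 of 50 rare k-mers are homologous even when no
#' background statistics are available).
#'
#' @param ids,counts Candidates and shared counts from
#'   [gather_candidates()].
#' @param fit A [fit_background()] object.
#' @param threshold Corrected-probability threshold (default 0.9).
#' @param max_possible Maximum possible shared count for the focal
#'   sequence (its number of selected rare k-mers); used by the degenerate
#'   fallback.
#' @return Integer vector of candidate ids declared homologous.
#' @export
homology_probabilities <- function(ids, counts, fit, threshold = 0.9,
                                   max_possible = 50L) {
  if (length(ids) == 0L) return(integer(0))
  half_max <- 0.5 * max(1L, max_possible)
  if (fit$degenerate ||
      (isTRUE(fit$saturated) && stats::median(counts) >= half_max)) {
    # No separable background: either too few points to fit, or the
    # typical candidate already shares half the focal's rare k-mers and
    # the observed background runs to the highest shared count - the
    # signature of an all-homologous input where rarity carries no signal.
    # Sequences sharing an unusually high number of rare k-mers (at
    # least half the maximum possible) are declared homologous.
    return(ids[counts >= half_max])
  }
  o <- order(-counts)
  p <- pmax(0, 1 - exp(fit$intercept + fit$slope * counts[o]))
  if (!is.null(fit$bg_end)) p[counts[o] <= fit$bg_end] <- 0
  corrected <- cumprod(p)
  ids[o][corrected >= threshold]
}

#' Partition sequences into disjoint sets of detectable homology
#'
#' Runs a stack-based depth-first search over the declared-homologous
#' relation: each sequence's candidate expansion (gather, background fit,
#' probability correction) is executed at most once, and partitions are
#' the connected components of the relation treated as undirected
#' (single-linkage homology). Sequences with no rare k-mers become their
#' own singleton partitions.
#'
#' @param table A [build_rare_table()] object.
#' @param params A [clust_params()] object.
#' @return A list of class `partition_assignment` with `partition`
#'   (integer id per sequence, 1..P) and `sizes`.
#' @export
partition_sequences <- function(table, params = clust_params()) {
  n <- table$n
  n_rare <- diff(table$seq_ptr)
  part <- integer(n)
  expanded <- logical(n)
  # union-find over provisional partition ids, to honor undirected linkage
  # when a later expansion declares a sequence already assigned elsewhere
  uf <- integer(0)
  uf_find <- function(z) {
    while (uf[z] != z) {
      uf[z] <<- uf[uf[z]]
      z <- uf[z]
    }
    z
  }
  pid <- 0L
  for (i in seq_len(n)) {
    if (part[i] != 0L) next
    pid <- pid + 1L
    uf[pid] <- pid
    part[i] <- pid
    stack <- i
    while (length(stack) > 0L) {
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (expanded[j]) next
      expanded[j] <- TRUE
      g <- gather_candidates(j, table, params$A)
      if (length(g$ids) == 0L) next
      fit <- fit_background(g$hist)
      hom <- homology_probabilities(g$ids, g$counts, fit,
                                    params$homology_prob, n_rare[j])
      if (length(hom) == 0L) next
      fresh <- hom[part[hom] == 0L]
      if (length(fresh) > 0L) {
        part[fresh] <- pid
        stack <- c(stack, fresh)
      }
      other <- hom[part[hom] != 0L & part[hom] != pid]
      for (h in other) {
        ra <- uf_find(part[h])
        rb <- uf_find(pid)
        if (ra != rb) uf[ra] <- rb
      }
    }
  }
  roots <- vapply(seq_len(pid), uf_find, 0L)
  remap <- match(roots, unique(roots))
  part <- remap[part]
  structure(list(partition = part, sizes = tabulate(part)),
            class = "partition_assignment")
}

#' @export
print.partition_assignment <- function(x, ...) {
  cat(sprintf("<partition_assignment> %d sequences in %d partitions (largest %d)\n",
              length(x$partition), length(x$sizes), max(x$sizes)))
  invisible(x)
}
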