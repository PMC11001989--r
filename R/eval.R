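#' Label consistency of a clustering
#'
#' The average fraction of each cluster sharing the cluster's most
#' frequent label, weighted by cluster size minus one:
#' `sum(f_i * (m_i - 1)) / sum(m_i - 1)`. Singleton clusters, which are
#' 100% consistent by definition, carry zero weight and have no influence
#' on the average. An all-singleton clustering is defined as perfectly
#' consistent (1).
#'
#' @param clusters Cluster assignment per sequence.
#' @param labels Ground-truth label per sequence.
#' @return Consistency in `[0, 1]`.
#' @examples
#' label_consistency(c(1, 1, 1, 2), c("a", "a", "b", "c"))  # 2/3
#' @export
label_consistency <- function(clusters, labels) {
  stopifnot(length(clusters) == length(labels))
  if (length(clusters) == 0L) return(NA_real_)
  tab <- table(clusters, labels)
  m <- rowSums(tab)
  f <- apply(tab, 1L, max) / m
  w <- m - 1
  if (sum(w) == 0) return(1)
  sum(f * w) / sum(w)
}

#' Fraction of clustered pairs below the similarity threshold
#'
#' Samples up to `max_pairs` pairs of sequences belonging to the same
#' cluster (uniformly over all within-cluster pairs; exhaustively when
#' fewer exist), computes their aligned identity under `config`, and
#' returns the fraction falling below `threshold`. Inexact clustering
#' establishes linkage only to one representative per cluster, so some
#' member pairs are expected to fall below the threshold.
#'
#' @param clusters Cluster assignment per sequence.
#' @param seqs Character vector of the sequences.
#' @param threshold Similarity threshold.
#' @param config A [sim_config()].
#' @param max_pairs Maximum sampled pairs (default 10000).
#' @param k Matching k-mer length; defaults to a plan over `seqs`.
#' @return A list with `rate`, `n_pairs`, and `defined` (`FALSE` when no
#'   within-cluster pair exists).
#' @export
violation_rate <- function(clusters, seqs, threshold,
                           config = sim_config(), max_pairs = 10000L,
                           k = NULL) {
  stopifnot(length(clusters) == length(seqs))
  sizes <- table(clusters)
  eligible <- names(sizes)[sizes >= 2]
  if (length(eligible) == 0L)
    return(list(rate = NA_real_, n_pairs = 0L, defined = FALSE))
  kind <- detect_alphabet(seqs)
  ab <- make_alphabet(kind)
  scoring <- scoring_scheme(ab)
  if (is.null(k))
    k <- kmer_plan(nchar(seqs), kind)$k_match
  by_cluster <- split(seq_along(clusters), clusters)
  by_cluster <- by_cluster[eligible]
  npairs_per <- vapply(by_cluster, function(m) choose(length(m), 2), 0)
  total <- sum(npairs_per)
  if (total <= max_pairs) {
    pairs <- do.call(rbind, lapply(by_cluster, function(m) {
      if (length(m) < 2L) return(NULL)
      t(utils::combn(m, 2L))
    }))
  } else {
    ci <- sample.int(length(by_cluster), max_pairs, replace = TRUE,
                     prob = npairs_per)
    pairs <- t(vapply(ci, function(c) {
      m <- by_cluster[[c]]
      m[sample.int(length(m), 2L)]
    }, c(0L, 0L)))
  }
  below <- logical(nrow(pairs))
  for (t in seq_len(nrow(pairs))) {
    ps <- pair_similarity(seqs[[pairs[t, 1L]]], seqs[[pairs[t, 2L]]],
                          k = k, alphabet = ab, config = config,
                          scoring = scoring)
    below[t] <- ps$identity < threshold
  }
  list(rate = mean(below), n_pairs = nrow(pairs), defined = TRUE)
}

#' Normalized and adjusted mutual information
#'
#' Standard information-theoretic agreement between a clustering and
#' ground-truth labels, computed from their contingency table. NMI is the
#' mutual information normalized by the arithmetic mean of the two
#' entropies; AMI additionally subtracts the expected mutual information
#' of random contingency tables with the same margins (the hypergeometric
#' model). When both the clustering and the labels are single groups
#' (zero entropy on both sides) the agreement is defined as 1.
#'
#' @param clusters Cluster assignment per sequence.
#' @param labels Ground-truth label per sequence.
#' @return A list with `ami` and `nmi`.
#' @export
mutual_information_scores <- function(clusters, labels) {
  stopifnot(length(clusters) == length(labels))
  n <- length(clusters)
  tab <- table(clusters, labels)
  a <- rowSums(tab)
  b <- colSums(tab)
  nz <- tab > 0
  pij <- tab / n
  pa <- a / n
  pb <- b / n
  mi <- sum(pij[nz] * log(pij[nz] / outer(pa, pb)[nz]))
  ha <- -sum(pa[pa > 0] * log(pa[pa > 0]))
  hb <- -sum(pb[pb > 0] * log(pb[pb > 0]))
  denom <- (ha + hb) / 2
  nmi <- if (denom == 0) 1 else max(0, mi / denom)
  # expected MI under the hypergeometric (fixed-margins) model
  emi <- 0
  for (i in seq_along(a)) {
    for (j in seq_along(b)) {
      lo <- max(1, a[i] + b[j] - n)
      hi <- min(a[i], b[j])
      if (hi < lo) next
      for (nij in lo:hi) {
        lp <- lchoose(b[j], nij) + lchoose(n - b[j], a[i] - nij) -
          lchoose(n, a[i])
        emi <- emi + exp(lp) * (nij / n) * log(n * nij / (a[i] * b[j]))
      }
    }
  }
  ami_denom <- denom - emi
  ami <- if (denom == 0) 1
         else if (ami_denom <= 0) 0
         else (mi - emi) / ami_denom
  list(ami = unname(ami), nmi = unname(nmi))
}

#' Empirical scaling exponent from timed runs
#'
#' Least-squares slope of time against input size in log-log space over
#' the largest four measured sizes; the slope estimates the order x of
#' the empirical time complexity O(N^x).
#'
#' @param sizes Input sizes (>= 4 values, positive).
#' @param times Elapsed times (positive).
#' @return The slope.
#' @examples
#' scaling_exponent(c(1e3, 2e3, 4e3, 8e3), c(1, 2, 4, 8))  # 1
#' @export
scaling_exponent <- function(sizes, times) {
  stopifnot(length(sizes) == length(times), length(sizes) >= 4L)
  if (any(sizes <= 0) || any(times <= 0))
    stop("'sizes' and 'times' must be positive")
  o <- order(-sizes)
  top <- o[1:4]
  xs <- log(sizes[top])
  ys <- log(times[top])
  sum((xs - mean(xs)) * (ys - mean(ys))) / sum((xs - mean(xs))^2)
}

#' Evaluate a clustering against ground-truth labels
#'
#' Convenience wrapper assembling the evaluation report: mutual
#' information scores, label consistency, cluster count, and (optionally)
#' the threshold-violation rate.
#'
#' @param object A [relclust()] object.
#' @param labels Ground-truth label per input sequence (recycled against
#'   the object's cluster table by `id` when named).
#' @param violation Also sample the threshold-violation rate (slower).
#' @param max_pairs Pairs for the violation estimate.
#' @return A list of class `relclust_eval`.
#' @export
evaluate_clustering <- function(object, labels, violation = FALSE,
                                max_pairs = 10000L) {
  stopifnot(inherits(object, "relclust"))
  cl <- object$table$cluster
  if (!is.null(names(labels))) labels <- labels[object$table$id]
  stopifnot(length(labels) == length(cl))
  mis <- mutual_information_scores(cl, labels)
  out <- list(ami = mis$ami, nmi = mis$nmi,
              consistency = label_consistency(cl, labels),
              n_clusters = object$n_clusters)
  if (violation) {
    vr <- violation_rate(cl, object$sequences, object$threshold,
                         object$config, max_pairs)
    out$violation_rate <- vr$rate
    out$violation_pairs <- vr$n_pairs
  }
  class(out) <- "relclust_eval"
  out
}

#' @export
print.relclust_eval <- function(x, ...) {
  cat(sprintf("Clustering evaluation: %d clusters\n", x$n_clusters))
  cat(sprintf("  NMI %.4f, AMI %.4f, label consistency %.4f\n",
              x$nmi, x$ami, x$consistency))
  if (!is.null(x$violation_rate))
    cat(sprintf("  threshold violations: %.2f%% of %d sampled pairs\n",
                100 * x$violation_rate, x$violation_pairs))
  invisible(x)
}
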