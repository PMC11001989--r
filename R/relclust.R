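#' Cluster biological sequences in linear time by relatedness sorting
#'
#' Threshold-based inexact clustering of nucleotide or amino-acid
#' sequences. The algorithm runs in three phases, each bounded by a
#' constant amount of work per sequence: (1) sequences are separated into
#' disjoint partitions of detectable homology by counting shared rare
#' k-mers against an empirically fitted background; (2) each partition is
#' iteratively sorted by relatedness using one-dimensional projections of
#' relative k-mer-distance vectors, while a sample of pairs is aligned to
#' calibrate the relationship between k-mer similarity and aligned
#' identity; (3) sequences are visited in order of decreasing length and
#' greedily assigned to cluster representatives, with candidates drawn
#' from rare-k-mer sharing and rank proximity in proportion to each
#' strategy's yield. Every clustered sequence satisfies the similarity
#' threshold and minimum coverage against its cluster representative,
#' which is always the longest member of its cluster.
#'
#' @param x Sequences: a named character vector, a `Biostrings` XStringSet,
#'   or the path to a (optionally gzipped) FASTA file.
#' @param threshold Similarity threshold in (0, 1]: members must reach at
#'   least this aligned identity to their representative.
#' @param alphabet `"auto"` (default), `"DNA"` or `"AA"`.
#' @param config A [sim_config()]: similarity definition options.
#' @param params A [clust_params()]: the bounding constants A, B, C, E and
#'   related settings.
#' @param seed Integer seed; with the same seed the clustering is fully
#'   reproducible. `NULL` leaves the random number generator untouched.
#' @param dereplicate Collapse exact duplicate sequences before clustering
#'   and re-expand them in the output (default `TRUE`).
#' @param scoring Optional [scoring_scheme()]; defaults to the standard
#'   scheme for the detected alphabet.
#' @param verbose Print per-phase progress.
#' @return An object of class `relclust`; see [print.relclust()],
#'   [summary.relclust()], [as.data.frame.relclust()],
#'   [predict.relclust()].
#' @examples
#' fam <- generate_families(n_families = 3, members = 5,
#'                          ancestor_length = 120, seed = 1)
#' fit <- relclust(fam$sequences, threshold = 0.9, seed = 1)
#' fit
#' @export
relclust <- function(x, threshold = 0.9,
                     alphabet = c("auto", "DNA", "AA"),
                     config = sim_config(), params = clust_params(),
                     seed = NULL, dereplicate = TRUE, scoring = NULL,
                     verbose = FALSE) {
  cl <- match.call()
  alphabet <- match.arg(alphabet)
  stopifnot(is.numeric(threshold), threshold > 0, threshold <= 1)
  seqs <- as_sequences(x)
  n_input <- length(seqs)
  if (n_input == 0L) {
    return(empty_relclust(cl, threshold, config, params))
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  t0 <- proc.time()[["elapsed"]]
  timings <- c()

  # dereplicate exact duplicates
  if (dereplicate) {
    uix <- which(!duplicated(seqs))
    dup_map <- match(seqs, seqs[uix])
  } else {
    uix <- seq_len(n_input)
    dup_map <- seq_len(n_input)
  }
  useqs <- seqs[uix]
  n <- length(useqs)

  kind <- if (alphabet == "auto") detect_alphabet(useqs) else alphabet
  ab_full <- make_alphabet(kind)
  ab_rare <- make_alphabet(if (kind == "DNA") "DNA" else "AA10")
  if (is.null(scoring)) scoring <- scoring_scheme(ab_full)
  codes <- encode_sequences(useqs, ab_full)
  lens <- nchar(useqs)
  plan <- kmer_plan(lens, kind, params$rare_per_seq)

  # k-mer indices in the full alphabet for matching
  kidx <- lapply(codes, function(cv)
    encode_kmers_cpp(cv, plan$k_match, plan$x_match))
  seqdata <- list(codes = codes,
                  kmers = lapply(kidx, `[[`, "kmers"),
                  positions = lapply(kidx, `[[`, "positions"),
                  lens = as.integer(lens), k = plan$k_match,
                  names = names(useqs))
  timings["encode"] <- proc.time()[["elapsed"]] - t0

  # rare k-mers in the phase-1 alphabet
  t1 <- proc.time()[["elapsed"]]
  rare_codes <- if (kind == "DNA") codes else encode_sequences(useqs, ab_rare)
  bins <- lapply(rare_codes, function(cv) {
    km <- encode_kmers_cpp(cv, plan$k_rare, plan$x_rare)$kmers
    hash_kmer_cpp(km, plan$s)
  })
  freq <- tabulate(unlist(bins, use.names = FALSE) + 1L, nbins = plan$s)
  selections <- select_rare_kmers(bins, freq, params$rare_per_seq)
  table <- build_rare_table(selections)

  part <- partition_sequences(table, params)
  timings["phase1"] <- proc.time()[["elapsed"]] - t1
  if (verbose)
    message(sprintf("phase 1: %d partitions (largest %d) [%.1fs]",
                    length(part$sizes), max(part$sizes), timings["phase1"]))

  # phase 2: relatedness sorting within partitions, in partition order
  t2 <- proc.time()[["elapsed"]]
  final_order <- integer(0)
  for (pid in seq_along(part$sizes)) {
    members <- which(part$partition == pid)
    if (length(members) < 2L) {
      final_order <- c(final_order, members)
    } else {
      ph2 <- run_phase2(members, seqdata, seqdata$lens, plan$k_match, params)
      final_order <- c(final_order, ph2$order)
    }
  }
  rank_pos <- integer(n)
  rank_pos[final_order] <- seq_len(n)

  # calibration: aligned sample of within-partition pairs
  pairs <- sample_calibration_pairs(part$partition, final_order,
                                    params$calibration_pairs)
  calib_df <- NULL
  if (nrow(pairs) > 0L) {
    ks <- numeric(nrow(pairs))
    id <- numeric(nrow(pairs))
    for (t in seq_len(nrow(pairs))) {
      i <- pairs[t, 1L]; j <- pairs[t, 2L]
      sims <- kmer_sim_many_cpp(seqdata$kmers, seqdata$positions,
                                seqdata$lens, i, j, seqdata$k)
      ks[t] <- sims[1L, 1L]
      aln <- align_pair_ids(i, j, seqdata, scoring)
      id[t] <- percent_identity(aln, config)$identity
    }
    calib_df <- data.frame(ksim = ks, identity = id,
                           pass = id >= threshold)
  }
  calibration <- calibrate_identity(
    if (is.null(calib_df)) numeric(0) else calib_df$ksim,
    if (is.null(calib_df)) logical(0) else calib_df$pass,
    threshold, floor = params$align_prob_floor)
  timings["phase2"] <- proc.time()[["elapsed"]] - t2
  if (verbose)
    message(sprintf("phase 2: calibrated on %d pairs (boundary %.3f) [%.1fs]",
                    calibration$n_pairs,
                    if (calibration$fallback) 0 else calibration$boundary,
                    timings["phase2"]))

  # phase 3: greedy assignment in decreasing length order
  t3 <- proc.time()[["elapsed"]]
  vorder <- visit_order(lens)
  cluster_of <- rep(NA_integer_, n)
  rep_of_seq <- rep(NA_integer_, n)   # representative id of each seq's cluster
  cluster_rep <- integer(0)
  identity <- rep(NA_real_, n)
  aligned <- logical(n)
  yields <- c(rare = 1L, sort = 1L)   # +1 smoothing
  attributed <- c(rare = 0L, sort = 0L, both = 0L)
  n_aligned_total <- 0L
  for (i in vorder) {
    if (length(seqdata$kmers[[i]]) == 0L) {
      cluster_rep <- c(cluster_rep, i)
      cluster_of[i] <- length(cluster_rep)
      rep_of_seq[i] <- i
      identity[i] <- 1
      next
    }
    quota <- candidate_quota(yields[["rare"]], yields[["sort"]], params$C)
    cand <- draw_candidates(i, rank_pos, final_order, table, rep_of_seq,
                            quota, params$A, params$C)
    res <- assign_sequence(i, cand$reps, seqdata, calibration, threshold,
                           config, scoring, params$E,
                           params$align_prob_floor)
    n_aligned_total <- n_aligned_total + res$n_aligned
    if (is.na(res$rep)) {
      cluster_rep <- c(cluster_rep, i)
      cluster_of[i] <- length(cluster_rep)
      rep_of_seq[i] <- i
      identity[i] <- 1
    } else {
      cluster_of[i] <- cluster_of[res$rep]
      rep_of_seq[i] <- res$rep
      identity[i] <- res$identity
      aligned[i] <- res$aligned
      w <- which(cand$reps == res$rep)
      fr <- cand$from_rare[w]
      fs <- cand$from_sort[w]
      if (fr) yields[["rare"]] <- yields[["rare"]] + 1L
      if (fs) yields[["sort"]] <- yields[["sort"]] + 1L
      if (fr && fs) attributed[["both"]] <- attributed[["both"]] + 1L
      else if (fr) attributed[["rare"]] <- attributed[["rare"]] + 1L
      else if (fs) attributed[["sort"]] <- attributed[["sort"]] + 1L
    }
  }
  timings["phase3"] <- proc.time()[["elapsed"]] - t3

  # re-expand duplicates onto the input
  cluster_all <- cluster_of[dup_map]
  rep_all <- rep_of_seq[dup_map]
  identity_all <- identity[dup_map]
  is_rep <- seq_len(n_input) %in% uix[cluster_rep]
  tab <- data.frame(
    id = if (is.null(names(seqs))) as.character(seq_len(n_input)) else names(seqs),
    cluster = cluster_all,
    is_representative = is_rep,
    identity_to_representative = identity_all,
    stringsAsFactors = FALSE)

  out <- list(call = cl, n = n_input, n_unique = n, threshold = threshold,
              alphabet = kind, config = config, params = params,
              plan = plan, table = tab,
              cluster = stats::setNames(cluster_all, tab$id),
              representatives = uix[cluster_rep],
              sizes = tabulate(cluster_all),
              n_clusters = length(cluster_rep),
              partition = part$partition[dup_map],
              n_partitions = length(part$sizes),
              order = final_order, rank_pos = rank_pos,
              calibration = calibration, calibration_pairs = calib_df,
              yields = yields - 1L, attributed = attributed,
              n_aligned = n_aligned_total,
              dup_map = dup_map, unique_index = uix,
              sequences = seqs, seqdata = seqdata, scoring = scoring,
              timings = timings)
  class(out) <- "relclust"
  out
}

empty_relclust <- function(cl, threshold, config, params) {
  structure(list(call = cl, n = 0L, n_unique = 0L, threshold = threshold,
                 config = config, params = params,
                 table = data.frame(id = character(0), cluster = integer(0),
                                    is_representative = logical(0),
                                    identity_to_representative = numeric(0)),
                 cluster = integer(0), representatives = integer(0),
                 sizes = integer(0), n_clusters = 0L,
                 yields = c(rare = 0L, sort = 0L),
                 attributed = c(rare = 0L, sort = 0L, both = 0L)),
            class = "relclust")
}

# coerce input to a named character vector of sequences
as_sequences <- function(x) {
  if (is.character(x) && length(x) == 1L && is.null(names(x)) &&
      file.exists(x)) {
    return(read_sequences(x))
  }
  if (methods::is(x, "XStringSet")) {
    out <- as.character(x)
    if (is.null(names(out))) names(out) <- as.character(seq_along(out))
    return(out)
  }
  stopifnot(is.character(x))
  if (is.null(names(x))) names(x) <- as.character(seq_along(x))
  x
}

# Calibration pair sampling: within-partition pairs biased 50/50 between
# rank-adjacent and random pairs, plus a smaller set of between-partition
# pairs (known to be unrelated) so that both sides of the threshold are
# represented even when every partition is internally tight.
sample_calibration_pairs <- function(partition, final_order, npairs) {
  n <- length(partition)
  adj <- which(partition[final_order[-n]] == partition[final_order[-1L]])
  sizes <- tabulate(partition)
  multi <- which(sizes[partition] >= 2L)
  if (length(adj) == 0L || length(multi) == 0L)
    return(matrix(integer(0), 0, 2))
  n_adj <- ceiling(npairs / 2)
  n_rnd <- npairs - n_adj
  t_adj <- adj[sample.int(length(adj), n_adj, replace = TRUE)]
  p1 <- final_order[t_adj]
  p2 <- final_order[t_adj + 1L]
  a <- multi[sample.int(length(multi), n_rnd, replace = TRUE)]
  b <- vapply(a, function(i) {
    others <- which(partition == partition[i])
    others <- others[others != i]
    others[sample.int(length(others), 1L)]
  }, 0L)
  out <- cbind(c(p1, a), c(p2, b))
  if (max(partition) >= 2L && n >= 2L) {
    n_btw <- max(1L, npairs %/% 4L)
    u <- sample.int(n, n_btw, replace = TRUE)
    v <- vapply(u, function(i) {
      others <- which(partition != partition[i])
      if (length(others) == 0L) return(NA_integer_)
      others[sample.int(length(others), 1L)]
    }, 0L)
    keep <- !is.na(v)
    out <- rbind(out, cbind(u[keep], v[keep]))
  }
  out
}

#' @export
print.relclust <- function(x, ...) {
  cat(sprintf("Sequence clustering by relatedness sorting\n"))
  cat(sprintf("  %d sequences (%d unique), threshold %.4g, %s alphabet\n",
              x$n, x$n_unique, x$threshold,
              if (is.null(x$alphabet)) "?" else x$alphabet))
  cat(sprintf("  %d clusters (largest %d); %d singletons\n",
              x$n_clusters,
              if (length(x$sizes)) max(x$sizes) else 0L,
              sum(x$sizes == 1L)))
  if (!is.null(x$attributed)) {
    cat(sprintf("  strategy yields: %d rare k-mer, %d relatedness sorting, %d both\n",
                x$attributed[["rare"]], x$attributed[["sort"]],
                x$attributed[["both"]]))
  }
  invisible(x)
}

#' Summarize a clustering
#'
#' @param object A [relclust()] object.
#' @param ... Unused.
#' @return A list of class `summary.relclust` with cluster counts, size
#'   quantiles, strategy yields, partition counts, calibration summary and
#'   phase timings.
#' @method summary relclust
#' @export
summary.relclust <- function(object, ...) {
  out <- list(n = object$n, n_unique = object$n_unique,
              threshold = object$threshold,
              n_clusters = object$n_clusters,
              size_summary = summary(object$sizes),
              singletons = sum(object$sizes == 1L),
              n_partitions = object$n_partitions,
              yields = object$yields, attributed = object$attributed,
              n_aligned = object$n_aligned,
              calibration = object$calibration,
              timings = object$timings)
  class(out) <- "summary.relclust"
  out
}

#' @export
print.summary.relclust <- function(x, ...) {
  cat(sprintf("Clustering of %d sequences (%d unique) at threshold %.4g\n",
              x$n, x$n_unique, x$threshold))
  cat(sprintf("  clusters: %d (%d singletons); partitions: %s\n",
              x$n_clusters, x$singletons,
              if (is.null(x$n_partitions)) "-" else x$n_partitions))
  cat("  cluster sizes: ")
  print(x$size_summary)
  if (!is.null(x$attributed))
    cat(sprintf("  assigned via rare k-mers: %d, relatedness sorting: %d, both: %d\n",
                x$attributed[["rare"]], x$attributed[["sort"]],
                x$attributed[["both"]]))
  if (!is.null(x$calibration)) print(x$calibration)
  if (!is.null(x$timings)) {
    cat("  timings (s): ")
    cat(paste(sprintf("%s %.1f", names(x$timings), x$timings),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Cluster table of a clustering
#'
#' @param x A [relclust()] object.
#' @param ... Unused.
#' @return A data frame with columns `id`, `cluster`,
#'   `is_representative`, and `identity_to_representative` (aligned
#'   identity when the assignment was confirmed by alignment, otherwise
#'   the screening k-mer similarity, which is a lower bound).
#' @method as.data.frame relclust
#' @export
as.data.frame.relclust <- function(x, ...) {
  x$table
}

#' Assign new sequences to an existing clustering
#'
#' Screens each new sequence against all cluster representatives by k-mer
#' similarity and confirms borderline candidates by anchored alignment,
#' using the fitted calibration. Sequences meeting the threshold join the
#' best representative's cluster; others are reported unassigned (`NA`).
#'
#' @param object A [relclust()] object.
#' @param newdata Character vector of sequences.
#' @param ... Unused.
#' @return Integer vector of cluster ids (`NA` = would found a new
#'   cluster), with the matched representative id as an attribute.
#' @export
predict.relclust <- function(object, newdata, ...) {
  stopifnot(is.character(newdata))
  if (object$n_clusters == 0L)
    return(rep(NA_integer_, length(newdata)))
  sd <- object$seqdata
  ab <- make_alphabet(object$alphabet)
  reps <- match(object$representatives, object$unique_index)
  out <- integer(length(newdata))
  repid <- integer(length(newdata))
  for (t in seq_along(newdata)) {
    codes <- ab$lookup[utf8ToInt(newdata[[t]]) + 1L]
    ki <- encode_kmers_cpp(codes, sd$k, ab$size)
    aug <- list(codes = c(sd$codes, list(codes)),
                kmers = c(sd$kmers, list(ki$kmers)),
                positions = c(sd$positions, list(ki$positions)),
                lens = c(sd$lens, length(codes)), k = sd$k)
    i <- length(aug$lens)
    res <- assign_sequence(i, reps, aug, object$calibration,
                           object$threshold, object$config, object$scoring,
                           object$params$E, object$params$align_prob_floor)
    out[t] <- if (is.na(res$rep)) NA_integer_ else
      object$cluster[object$unique_index[res$rep]]
    repid[t] <- if (is.na(res$rep)) NA_integer_ else res$rep
  }
  attr(out, "representative") <- repid
  out
}

#' Diagnostic plots for a clustering
#'
#' `which = 1` draws the cluster-size distribution; `which = 2` draws the
#' calibration sample (k-mer similarity against aligned identity) with the
#' fitted logistic pass-probability curve and the alignment boundary.
#'
#' @param x A [relclust()] object.
#' @param which Plot selection (1, 2 or both).
#' @param ... Passed to the underlying plotting functions.
#' @method plot relclust
#' @export
plot.relclust <- function(x, which = 1L, ...) {
  if (1L %in% which) {
    graphics::plot(table(factor(x$sizes, levels = seq_len(max(x$sizes)))),
                   xlab = "cluster size", ylab = "clusters",
                   main = "Cluster size distribution", ...)
  }
  if (2L %in% which && !is.null(x$calibration_pairs)) {
    df <- x$calibration_pairs
    graphics::plot(df$ksim, df$identity,
                   col = ifelse(df$pass, "forestgreen", "grey40"),
                   pch = 20, xlab = "k-mer similarity",
                   ylab = "aligned identity",
                   main = "Identity calibration", ...)
    graphics::abline(h = x$threshold, lty = 2)
    if (!x$calibration$fallback) {
      xs <- seq(0, 1, length.out = 200)
      graphics::lines(xs, predict(x$calibration, xs), col = "red3")
      graphics::abline(v = x$calibration$boundary, col = "red3", lty = 3)
    }
  }
  invisible(x)
}
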