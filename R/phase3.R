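#' Processing order for clustering
#'
#' Sequences are visited in order of decreasing length (stable: ties keep
#' input order) so that the cluster representative is always the longest
#' sequence in its cluster.
#'
#' @param lengths Integer vector of sequence lengths.
#' @return Integer permutation: indices in processing order.
#' @export
visit_order <- function(lengths) {
  order(-as.numeric(lengths))
}

#' Split the candidate quota between the two strategies
#'
#' The total candidate budget `C` is divided between the rare-k-mer and
#' relatedness-sorting strategies in proportion to the clustered sequences
#' each has yielded so far. Yield counters start at 1 (+1 smoothing) so
#' neither strategy starves before its first success.
#'
#' @param yield_rare,yield_sort Clustered-sequence counts per strategy.
#' @param C Total candidate budget.
#' @return Integer vector `c(rare, sort)` summing to `C`.
#' @export
candidate_quota <- function(yield_rare, yield_sort, C = 2000L) {
  q_rare <- as.integer(round(C * yield_rare / (yield_rare + yield_sort)))
  c(rare = q_rare, sort = as.integer(C) - q_rare)
}

#' Draw candidate cluster representatives for one sequence
#'
#' Combines the two linear-time strategies: (1) rare-k-mer sharing, drawn
#' exactly as in phase 1 and ordered by descending shared count; (2)
#' relatedness-rank proximity, taking previously processed sequences
#' symmetrically (nearest first) from a window of +/- C/2 positions around
#' the sequence's final rank. Candidates are mapped to their current
#' cluster representatives and deduplicated, keeping the origin flags of
#' every candidate that introduced each representative.
#'
#' @param i Focal sequence id.
#' @param rank_pos Global rank position per sequence (phase-2 order).
#' @param ordvec Sequence ids in global rank order.
#' @param table A [build_rare_table()] object.
#' @param rep_of_seq Representative id of each processed sequence's
#'   cluster (`NA` for unprocessed sequences).
#' @param quota Integer vector `c(rare, sort)` from [candidate_quota()].
#' @param A Candidate limit for the rare-k-mer gather.
#' @param C Total candidate cap (window half-width is `C/2`).
#' @return A list with `reps` (unique representative ids) and logical
#'   vectors `from_rare`, `from_sort`.
#' @export
draw_candidates <- function(i, rank_pos, ordvec, table, rep_of_seq,
                            quota, A = 20000L, C = 2000L) {
  n <- length(rank_pos)
  # relatedness-sorting strategy: processed neighbors in rank order
  p <- rank_pos[i]
  lo <- max(1L, p - as.integer(C / 2))
  hi <- min(n, p + as.integer(C / 2))
  win <- ordvec[lo:hi]
  win <- win[win != i]
  win <- win[!is.na(rep_of_seq[win])]
  if (length(win) > 1L) win <- win[order(abs(rank_pos[win] - p))]
  sort_ids <- win[seq_len(min(quota[["sort"]], length(win)))]
  # rare-k-mer strategy: highest shared counts first
  g <- gather_candidates(i, table, A)
  rare_ids <- integer(0)
  if (length(g$ids) > 0L) {
    cand <- g$ids[!is.na(rep_of_seq[g$ids])]
    cnts <- g$counts[!is.na(rep_of_seq[g$ids])]
    if (length(cand) > 0L) {
      o <- order(-cnts)
      rare_ids <- cand[o][seq_len(min(quota[["rare"]], length(cand)))]
    }
  }
  rep_rare <- unique(rep_of_seq[rare_ids])
  rep_sort <- unique(rep_of_seq[sort_ids])
  reps <- unique(c(rep_rare, rep_sort))
  if (length(reps) > C) reps <- reps[seq_len(C)]
  list(reps = reps,
       from_rare = reps %in% rep_rare,
       from_sort = reps %in% rep_sort)
}

#' Assign one sequence to a cluster representative
#'
#' Screening and confirmation: (a) k-mer similarity is computed to every
#' candidate representative, and if any meets the similarity threshold
#' with sufficient coverage the best such representative is used without
#' alignment (k-mer similarity is a lower bound on aligned identity under
#' matching definitions); (b) otherwise up to `E` representatives with the
#' highest k-mer similarities, restricted to those whose calibrated pass
#' probability is at least the alignment floor, are aligned in descending
#' k-mer similarity and the first representative confirmed to meet
#' threshold and coverage is used; (c) otherwise the sequence founds a
#' new cluster. Ties go to the representative seen first (older cluster).
#'
#' @param i Focal sequence id.
#' @param reps Candidate representative ids.
#' @param seqdata Internal sequence data (codes, k-mer indices, lengths).
#' @param calibration An [calibrate_identity()] object.
#' @param threshold Similarity threshold in (0, 1].
#' @param config A [sim_config()].
#' @param scoring A [scoring_scheme()].
#' @param E Alignment limit.
#' @param floor Alignment probability floor.
#' @return A list with `rep` (chosen representative id or `NA`),
#'   `identity` (screening k-mer similarity or aligned identity),
#'   `aligned` (logical), and `n_aligned`.
#' @keywords internal
assign_sequence <- function(i, reps, seqdata, calibration, threshold,
                            config, scoring, E = 200L, floor = 0.01) {
  if (length(reps) == 0L)
    return(list(rep = NA_integer_, identity = NA_real_, aligned = FALSE,
                n_aligned = 0L))
  sims <- kmer_sim_many_cpp(seqdata$kmers, seqdata$positions, seqdata$lens,
                            i, reps, seqdata$k)
  ks <- sims[, 1L]
  kcov <- sims[, 2L]
  ok <- which(ks >= threshold & kcov >= config$min_coverage)
  if (length(ok) > 0L) {
    best <- ok[order(-ks[ok])][1L]
    return(list(rep = reps[best], identity = ks[best], aligned = FALSE,
                n_aligned = 0L, ksim = ks, index = best))
  }
  prob <- predict(calibration, ks)
  cand <- which(prob >= floor & kcov >= config$min_coverage)
  if (length(cand) == 0L)
    return(list(rep = NA_integer_, identity = NA_real_, aligned = FALSE,
                n_aligned = 0L))
  cand <- cand[order(-ks[cand])]
  cand <- cand[seq_len(min(E, length(cand)))]
  n_aligned <- 0L
  for (j in cand) {
    r <- reps[j]
    aln <- align_pair_ids(i, r, seqdata, scoring)
    n_aligned <- n_aligned + 1L
    pid <- percent_identity(aln, config)
    if (pid$pass && pid$identity >= threshold) {
      # candidates are visited in descending k-mer similarity, so the
      # first confirmed representative is the greedy assignment
      return(list(rep = reps[j], identity = pid$identity, aligned = TRUE,
                  n_aligned = n_aligned, index = j))
    }
  }
  list(rep = NA_integer_, identity = NA_real_, aligned = TRUE,
       n_aligned = n_aligned)
}

# chain + anchored alignment between two sequences in internal seqdata form
align_pair_ids <- function(i, j, seqdata, scoring) {
  blocks <- match_blocks_cpp(seqdata$kmers[[i]], seqdata$positions[[i]],
                             seqdata$kmers[[j]], seqdata$positions[[j]],
                             seqdata$k)
  ch <- chain_blocks_cpp(blocks)
  out <- anchored_align_cpp(seqdata$codes[[i]], seqdata$codes[[j]],
                            ch$blocks, unname(scoring$substitution),
                            scoring$gap_open, scoring$gap_extend)
  out$len1 <- seqdata$lens[i]
  out$len2 <- seqdata$lens[j]
  class(out) <- "alignment_result"
  out
}
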