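#' Sample the first reference sequence of a sorting iteration
#'
#' Draws one index with probability proportional to `v * L`: sequences
#' that are still moving in rank order, and longer sequences, are
#' preferred. Falls back to a uniform draw when all weights are zero.
#'
#' @param v Rank-movement averages of the group members.
#' @param lens Sequence lengths of the group members.
#' @return A single index into the group.
#' @export
pick_first <- function(v, lens) {
  w <- v * lens
  n <- length(w)
  if (n == 1L) return(1L)
  if (!any(w > 0)) return(sample.int(n, 1L))
  sample.int(n, 1L, prob = w)
}

#' Sample the second reference sequence of a sorting iteration
#'
#' Draws one index with probability proportional to `d1 / (delta_ov + 1)`:
#' sequences dissimilar to the first reference but overlapping it
#' completely are preferred. `delta_ov` is the non-overlapping difference
#' in length with the first reference, `|L_first - L_j|`. Falls back to a
#' uniform draw when all weights are zero.
#'
#' @param d1 K-mer distances to the first reference.
#' @param delta_ov Non-overlapping length differences.
#' @param exclude Optional index never to select (the first reference).
#' @return A single index into the group.
#' @export
pick_second <- function(d1, delta_ov, exclude = NULL) {
  w <- d1 / (delta_ov + 1)
  if (!is.null(exclude)) w[exclude] <- 0
  n <- length(w)
  ok <- which(w > 0)
  if (length(ok) == 0L) {
    cand <- setdiff(seq_len(n), exclude)
    if (length(cand) == 0L) cand <- seq_len(n)
    return(cand[sample.int(length(cand), 1L)])
  }
  if (length(ok) == 1L) return(ok)
  sample.int(n, 1L, prob = w)
}

#' Relative distance vector from two reference sequences
#'
#' The difference `d1 - d2` of the k-mer distances to the two references;
#' it places each sequence along the axis between them (negative toward
#' the first, positive toward the second).
#'
#' @param d1,d2 K-mer distance vectors over the same group.
#' @return Numeric vector `d1 - d2`.
#' @export
relative_distances <- function(d1, d2) {
  stopifnot(length(d1) == length(d2))
  d1 - d2
}

#' Project two relative-distance vectors onto their shared axis
#'
#' Centers both vectors and projects the two-column data onto the leading
#' eigenvector of their 2x2 covariance matrix, i.e. retains the first
#' principal component. The sign is chosen so the result correlates
#' non-negatively with the previous vector, keeping the orientation stable
#' across iterations. If both vectors are (numerically) constant the
#' previous vector is kept.
#'
#' @param d_prev,d_new Relative-distance vectors over the same group.
#' @return Numeric vector: the projected combined coordinate.
#' @export
project_distances <- function(d_prev, d_new) {
  stopifnot(length(d_prev) == length(d_new))
  a <- d_prev - mean(d_prev)
  b <- d_new - mean(d_new)
  va <- mean(a * a)
  vb <- mean(b * b)
  cab <- mean(a * b)
  eps <- 1e-12
  if (va <= eps && vb <= eps) return(d_prev)
  # leading eigenvector of [[va, cab], [cab, vb]]
  tr <- va + vb
  disc <- sqrt(max(0, (va - vb)^2 + 4 * cab^2))
  lam <- (tr + disc) / 2
  e1 <- c(cab, lam - va)
  e2 <- c(lam - vb, cab)
  ev <- if (sum(e1 * e1) >= sum(e2 * e2)) e1 else e2
  if (sum(ev * ev) <= eps) ev <- if (va >= vb) c(1, 0) else c(0, 1)
  ev <- ev / sqrt(sum(ev * ev))
  d <- a * ev[1] + b * ev[2]
  if (sum(d * a) < 0) d <- -d
  d
}

#' Update rank order and movement average
#'
#' Sorts the projected coordinate (stable sort) to obtain the new rank
#' order, measures each sequence's absolute rank movement (capped at
#' `cap`), and updates the exponentially weighted moving average
#' `v = alpha * movement + (1 - alpha) * v_prev`, also capped at `cap`.
#'
#' @param D Projected coordinates.
#' @param prev_order Previous rank order (permutation of indices).
#' @param v_prev Previous movement averages.
#' @param alpha Smoothing parameter (default 0.05).
#' @param cap Movement cap, parameter C (default 2000).
#' @return A list with `order` (new permutation) and `v`.
#' @export
update_rank_and_v <- function(D, prev_order, v_prev, alpha = 0.05,
                              cap = 2000) {
  n <- length(D)
  o <- order(D)
  pos_new <- integer(n)
  pos_new[o] <- seq_len(n)
  pos_old <- integer(n)
  pos_old[prev_order] <- seq_len(n)
  movement <- pmin(abs(pos_new - pos_old), cap)
  v <- pmin(alpha * movement + (1 - alpha) * v_prev, cap)
  list(order = o, v = v)
}

#' Split a group at stabilized sequences
#'
#' A sequence whose movement average has stabilized at or below the
#' stability bound splits its group at its current rank position, provided
#' both resulting groups would contain at least `min_group` sequences.
#' Multiple cut points are applied greedily from left to right; splitting
#' recurses across iterations as more sequences stabilize.
#'
#' @param v_ranked Movement averages of the group in current rank order.
#' @param min_group Minimum size of each resulting group.
#' @param bound Stability bound (parameter C/2).
#' @return Integer vector of cut positions `r` (each group ends at `r`);
#'   empty when no split is allowed.
#' @export
split_groups <- function(v_ranked, min_group = 2000L, bound = 1000) {
  n <- length(v_ranked)
  stable <- which(v_ranked <= bound)
  cuts <- integer(0)
  last <- 0L
  for (r in stable) {
    if (r - last >= min_group && n - r >= min_group) {
      cuts <- c(cuts, r)
      last <- r
    }
  }
  cuts
}

#' Relatedness sorting of one partition
#'
#' Iteratively sorts the partition's sequences so that similar sequences
#' become rank neighbors. Each iteration picks two reference sequences
#' ([pick_first()], [pick_second()]), computes the relative k-mer-distance
#' vector, projects it together with the previous coordinate onto their
#' shared principal axis, re-ranks, and updates the movement average.
#' Groups whose members' movement all stabilized at or below `C/2` stop
#' sorting; stabilized sequences can split a group when both sides would
#' hold at least `min_group` sequences. Sorting stops after at most `B`
#' iterations per group. Partitions with fewer than 2 members are returned
#' unsorted.
#'
#' @param members Sequence indices of the partition (global ids).
#' @param kindex List of per-sequence k-mer index vectors (`kmers`,
#'   `positions` lists as built by the pipeline).
#' @param lens Global sequence lengths.
#' @param k Matching k-mer length.
#' @param params A [clust_params()] object.
#' @return A list with `order` (members in final rank order), `v`, and
#'   `iterations`.
#' @export
run_phase2 <- function(members, kindex, lens, k, params = clust_params()) {
  n <- length(members)
  if (n < 2L)
    return(list(order = members, v = rep(0, n), iterations = 0L))
  C <- params$C
  bound <- params$stability_bound
  ord <- seq_len(n)                 # local indices in rank order
  D <- rep(0, n)
  v <- rep(as.numeric(C), n)
  has_D <- rep(FALSE, n)            # whether D is initialized for a member
  # groups are contiguous rank segments; all start active
  groups <- list(list(start = 1L, end = n, active = TRUE))
  iter <- 0L
  L <- lens[members]
  while (iter < params$B && any(vapply(groups, `[[`, TRUE, "active"))) {
    iter <- iter + 1L
    next_groups <- list()
    for (g in groups) {
      if (!g$active) {
        next_groups[[length(next_groups) + 1L]] <- g
        next
      }
      a <- g$start
      b <- g$end
      loc <- ord[a:b]
      m <- length(loc)
      ids <- members[loc]
      first <- pick_first(v[loc], L[loc])
      sims1 <- kmer_sim_many_cpp(kindex$kmers, kindex$positions, lens,
                                 ids[first], ids, k)
      d1 <- 1 - sims1[, 1L]
      dov <- abs(L[loc] - L[loc][first])
      second <- pick_second(d1, dov, exclude = first)
      sims2 <- kmer_sim_many_cpp(kindex$kmers, kindex$positions, lens,
                                 ids[second], ids, k)
      d2 <- 1 - sims2[, 1L]
      d_new <- d1 - d2
      d_comb <- if (all(has_D[loc])) project_distances(D[loc], d_new) else d_new
      D[loc] <- d_comb
      has_D[loc] <- TRUE
      o <- order(d_comb)
      pos_new <- integer(m)
      pos_new[o] <- seq_len(m)
      movement <- pmin(abs(pos_new - seq_len(m)), C)
      v[loc] <- pmin(params$alpha * movement + (1 - params$alpha) * v[loc], C)
      ord[a:b] <- loc[o]
      # stability and splitting
      v_ranked <- v[ord[a:b]]
      cuts <- split_groups(v_ranked, params$min_group, bound)
      bounds <- c(0L, cuts, m)
      for (t in seq_len(length(bounds) - 1L)) {
        s_start <- a + bounds[t]
        s_end <- a + bounds[t + 1L] - 1L
        next_groups[[length(next_groups) + 1L]] <-
          list(start = s_start, end = s_end,
               active = max(v[ord[s_start:s_end]]) > bound)
      }
    }
    groups <- next_groups
  }
  list(order = members[ord], v = v, iterations = iter)
}
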