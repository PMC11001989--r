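#' K-mer length for pairwise matching
#'
#' Chooses the smallest k such that a k-mer match between two sequences is
#' expected by chance at most once per 100 k-mers for sequences at the 99th
#' percentile of input lengths: `k = ceiling(log_x(100 * w99))`. The result
#' is additionally capped so that `x^k` fits a signed 32-bit integer
#' (k <= 15 for x = 4, <= 9 for x = 10, <= 7 for x = 20); hitting the cap
#' emits a warning.
#'
#' @param w99 99th percentile of sequence lengths (>= 1).
#' @param x Alphabet size (4, 10 or 20).
#' @return Integer k-mer length.
#' @examples
#' choose_k_match(100, 4)   # 7
#' choose_k_match(500, 20)  # 4
#' @export
choose_k_match <- function(w99, x) {
  stopifnot(length(w99) == 1L, length(x) == 1L)
  if (!is.finite(w99) || w99 < 1) stop("'w99' must be >= 1")
  if (!is.finite(x) || x < 2) stop("'x' must be >= 2")
  k_from_target(100 * w99, x)
}

#' K-mer length for rare k-mers
#'
#' Chooses the smallest k such that each rare k-mer is expected to be found
#' by chance in fewer than 40 sequences (10% of the default candidate limit
#' of 20,000 divided by 50 rare k-mers per sequence):
#' `k = ceiling(log_x(50 * N / 40))`. Capped like [choose_k_match()].
#'
#' @param N Number of input sequences (>= 1).
#' @param x Size of the alphabet in which rare k-mers are formed (4 for
#'   nucleotides, 10 for the reduced amino-acid alphabet).
#' @return Integer k-mer length.
#' @examples
#' choose_k_rare(800, 10)       # 3
#' choose_k_rare(16e6, 4)       # 13
#' @export
choose_k_rare <- function(N, x) {
  stopifnot(length(N) == 1L, length(x) == 1L)
  if (!is.finite(N) || N < 1) stop("'N' must be >= 1")
  if (!is.finite(x) || x < 2) stop("'x' must be >= 2")
  k_from_target(50 * N / 40, x)
}

# smallest integer k with x^k >= target, capped at the 32-bit encoding width
k_from_target <- function(target, x) {
  k <- max(1L, as.integer(ceiling(log(target) / log(x) - 1e-9)))
  while (x^k < target) k <- k + 1L
  while (k > 1L && x^(k - 1L) >= target) k <- k - 1L
  cap <- encoding_cap(x)
  if (k > cap) {
    warning(sprintf("k = %d exceeds the 32-bit encoding cap for x = %d; using k = %d",
                    k, x, cap))
    k <- cap
  }
  k
}

# largest k with x^k <= 2^31 - 1 (codes are stored as R integers)
encoding_cap <- function(x) {
  as.integer(floor(log(2^31 - 1) / log(x) + 1e-9))
}

#' Plan k-mer lengths and hash-space size for an input set
#'
#' Computes the matching k-mer length from the 99th percentile of sequence
#' lengths, the rare-k-mer length from the number of sequences, and the
#' hash-space size `s = max(x_rare^(k_rare/2), mean length)`.
#'
#' @param lengths Integer vector of sequence lengths.
#' @param alphabet_kind `"DNA"` or `"AA"`. For amino acids, rare k-mers are
#'   formed in the reduced 10-letter alphabet while matching uses all 20.
#' @param rare_per_seq Rare k-mers selected per sequence (default 50).
#' @return A list of class `kmer_plan` with elements `k_match`, `k_rare`,
#'   `s`, `x_match`, `x_rare`, `w99`, `w_mean`, `n`, `rare_per_seq`.
#' @export
kmer_plan <- function(lengths, alphabet_kind = c("DNA", "AA"),
                      rare_per_seq = 50L) {
  alphabet_kind <- match.arg(alphabet_kind)
  stopifnot(length(lengths) >= 1L, all(lengths >= 0L), rare_per_seq >= 1L)
  x_match <- if (alphabet_kind == "DNA") 4L else 20L
  x_rare <- if (alphabet_kind == "DNA") 4L else 10L
  w99 <- max(1, as.numeric(stats::quantile(lengths, 0.99, names = FALSE)))
  w_mean <- max(1, mean(lengths))
  n <- length(lengths)
  k_match <- choose_k_match(w99, x_match)
  k_rare <- choose_k_rare(n, x_rare)
  s <- max(round(x_rare^(k_rare / 2)), round(w_mean))
  structure(list(k_match = k_match, k_rare = k_rare, s = s,
                 x_match = x_match, x_rare = x_rare,
                 w99 = w99, w_mean = w_mean, n = n,
                 rare_per_seq = as.integer(rare_per_seq)),
            class = "kmer_plan")
}

#' @export
print.kmer_plan <- function(x, ...) {
  cat(sprintf("<kmer_plan> N = %d, w99 = %g, k_match = %d (x = %d), k_rare = %d (x = %d), s = %g\n",
              x$n, x$w99, x$k_match, x$x_match, x$k_rare, x$x_rare, x$s))
  invisible(x)
}

#' Encode the k-mers of one sequence
#'
#' Converts every window of k consecutive mapped residues into a base-x
#' integer code, sorts the codes, and carries the original 0-based start
#' positions along. Windows containing symbols outside the alphabet are
#' omitted; sequences shorter than k yield an empty index.
#'
#' @param seq A single sequence (character) or an integer vector of 0-based
#'   letter codes (`NA` for unmapped symbols).
#' @param k K-mer length.
#' @param alphabet A [make_alphabet()] object (required when `seq` is a
#'   character string; otherwise only its size is used via `x`).
#' @param x Alphabet size; defaults to `alphabet$size`.
#' @return A list of class `kmer_index` with sorted integer `kmers` and
#'   matching 0-based `positions`.
#' @examples
#' a <- make_alphabet("DNA")
#' encode_kmers("ACGT", 2, a)$kmers  # 1 6 11
#' @export
encode_kmers <- function(seq, k, alphabet = NULL, x = alphabet$size) {
  if (is.character(seq)) {
    stopifnot(!is.null(alphabet))
    seq <- alphabet$lookup[utf8ToInt(seq) + 1L]
  }
  out <- encode_kmers_cpp(as.integer(seq), as.integer(k), as.integer(x))
  structure(list(kmers = out$kmers, positions = out$positions,
                 length = length(seq), k = as.integer(k)),
            class = "kmer_index")
}

#' Hash k-mer codes into a bounded bin space
#'
#' Each integer k-mer code seeds one step of a 32-bit xorshift generator
#' (shift triple 13/17/5) and the result is reduced modulo the hash-space
#' size `s`. The map is deterministic; a zero seed is remapped to a fixed
#' nonzero constant because zero is a fixed point of xorshift.
#'
#' @param codes Integer vector of k-mer codes.
#' @param s Hash-space size (>= 1).
#' @return Integer vector of 0-based bin indices in `[0, s)`.
#' @export
hash_kmer <- function(codes, s) {
  hash_kmer_cpp(as.integer(codes), as.numeric(s))
}

#' Select rare k-mers for each sequence
#'
#' Given each sequence's hash bins and a global per-bin frequency table,
#' selects up to `rare_per_seq` distinct bins per sequence by ascending
#' global frequency. Ties are broken toward the smaller bin index, which
#' makes the selection deterministic, so identical sequences always select
#' identical rare k-mers.
#'
#' @param bins List of integer vectors: the hash bins of each sequence's
#'   k-mers (0-based, in sequence order).
#' @param global_freq Integer vector of length `s`: total occurrences of
#'   each bin over all sequences.
#' @param rare_per_seq Maximum bins selected per sequence (default 50).
#' @return List of integer vectors of selected bins per sequence.
#' @export
select_rare_kmers <- function(bins, global_freq, rare_per_seq = 50L) {
  lapply(bins, function(b) {
    if (length(b) == 0L) return(integer(0))
    u <- unique(b)
    f <- global_freq[u + 1L]
    o <- order(f, u)
    u[o][seq_len(min(rare_per_seq, length(u)))]
  })
}

#' Build the rare-k-mer group index
#'
#' Flattens the per-sequence rare-k-mer selections into an inverted index:
#' a single `member` vector of sequence indices grouped by shared bin, with
#' per-slot `slot_start`/`slot_end` pointers into it. All sequences sharing
#' any of a given sequence's rare k-mers can then be looked up in time
#' proportional to the group sizes.
#'
#' @param selections List (one element per sequence) of selected bins, as
#'   returned by [select_rare_kmers()].
#' @return An object of class `rare_kmer_table`.
#' @export
build_rare_table <- function(selections) {
  n <- length(selections)
  nsel <- lengths(selections)
  slot_seq <- rep.int(seq_len(n), nsel)
  slot_bin <- as.integer(unlist(selections, use.names = FALSE))
  if (length(slot_bin) == 0L) {
    return(structure(list(member = integer(0), slot_start = integer(0),
                          slot_end = integer(0), slot_bin = integer(0),
                          seq_ptr = c(0L, cumsum(nsel)), n = n),
                     class = "rare_kmer_table"))
  }
  o <- order(slot_bin, slot_seq)
  member <- slot_seq[o]
  sorted_bin <- slot_bin[o]
  r <- rle(sorted_bin)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  gid <- rep.int(seq_along(r$lengths), r$lengths)
  slot_start_sorted <- starts[gid]
  slot_end_sorted <- ends[gid]
  slot_start <- integer(length(o))
  slot_end <- integer(length(o))
  slot_start[o] <- slot_start_sorted
  slot_end[o] <- slot_end_sorted
  structure(list(member = member, slot_start = slot_start,
                 slot_end = slot_end, slot_bin = slot_bin,
                 seq_ptr = c(0L, cumsum(nsel)), n = n),
            class = "rare_kmer_table")
}

#' @export
print.rare_kmer_table <- function(x, ...) {
  cat(sprintf("<rare_kmer_table> %d sequences, %d stored slots, %d distinct groups\n",
              x$n, length(x$member),
              if (length(x$slot_bin)) length(unique(x$slot_bin)) else 0L))
  invisible(x)
}

# slots (group pointers) of sequence i
rare_slots <- function(table, i) {
  from <- table$seq_ptr[i] + 1L
  to <- table$seq_ptr[i + 1L]
  if (to < from) return(list(start = integer(0), end = integer(0),
                             size = integer(0)))
  idx <- from:to
  st <- table$slot_start[idx]
  en <- table$slot_end[idx]
  list(start = st, end = en, size = en - st + 1L)
}
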