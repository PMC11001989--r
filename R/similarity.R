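#' Similarity definition options
#'
#' Controls how percent identity and coverage are computed from a pairwise
#' alignment. By default identity is the number of matching positions
#' divided by the length of the overlapping region, with each run of
#' consecutive gaps counted as a single mismatch (an event-based model of
#' indels), and pairs must overlap over at least 50% of the shorter
#' sequence.
#'
#' @param denominator `"overlap-region"` (default) or `"shortest-sequence"`.
#' @param gap_mode `"one-mismatch-per-run"` (default), `"per-position-mismatch"`,
#'   or `"ignore"`.
#' @param min_coverage Minimum aligned overlap as a fraction of the shorter
#'   sequence's length, in `[0, 1]` (default 0.5).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(denominator = c("overlap-region", "shortest-sequence"),
                       gap_mode = c("one-mismatch-per-run",
                                    "per-position-mismatch", "ignore"),
                       min_coverage = 0.5) {
  denominator <- match.arg(denominator)
  gap_mode <- match.arg(gap_mode)
  stopifnot(is.numeric(min_coverage), min_coverage >= 0, min_coverage <= 1)
  structure(list(denominator = denominator, gap_mode = gap_mode,
                 min_coverage = min_coverage),
            class = "sim_config")
}

#' Alignment scoring scheme
#'
#' For nucleotides: match = +3, transition (A<->G, C<->T) = 0, transversion
#' = -3. For amino acids the default substitution matrix is BLOSUM62 (as
#' shipped with Biostrings); a different matrix can be supplied directly or
#' read from an NCBI-style file with [read_score_matrix()]. Affine gap
#' penalties are gap open -10 and gap extend -2, with terminal gaps free.
#' Residues outside the alphabet score as the matrix minimum.
#'
#' @param alphabet A [make_alphabet()] object (`"DNA"` or `"AA"`).
#' @param matrix Optional substitution matrix with residue dimnames
#'   covering the alphabet (amino acids only).
#' @param match,transition,transversion Nucleotide scores.
#' @param gap_open,gap_extend Affine gap penalties (negative).
#' @return A list of class `scoring_scheme` with the substitution matrix
#'   indexed by 0-based letter codes.
#' @export
scoring_scheme <- function(alphabet, matrix = NULL,
                           match = 3, transition = 0, transversion = -3,
                           gap_open = -10, gap_extend = -2) {
  x <- alphabet$size
  if (alphabet$kind == "DNA") {
    sub <- base::matrix(transversion, x, x,
                        dimnames = list(alphabet$letters, alphabet$letters))
    diag(sub) <- match
    # purine <-> purine and pyrimidine <-> pyrimidine
    sub["A", "G"] <- sub["G", "A"] <- transition
    sub["C", "T"] <- sub["T", "C"] <- transition
  } else {
    if (is.null(matrix)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      matrix <- e$BLOSUM62
    }
    if (!all(alphabet$letters %in% rownames(matrix)))
      stop("substitution matrix does not cover the amino-acid alphabet")
    sub <- matrix[alphabet$letters, alphabet$letters]
  }
  if (!isSymmetric(unname(sub)))
    stop("substitution matrix must be symmetric")
  structure(list(substitution = sub, gap_open = gap_open,
                 gap_extend = gap_extend, kind = alphabet$kind),
            class = "scoring_scheme")
}

#' Read a substitution matrix in NCBI square-matrix text format
#'
#' Parses the whitespace-separated square matrix format used for BLAST
#' scoring matrices (comment lines start with `#`; the first row and column
#' hold residue labels).
#'
#' @param path Path to the matrix file.
#' @return A numeric matrix with residue dimnames.
#' @export
read_score_matrix <- function(path) {
  m <- as.matrix(utils::read.table(path, check.names = FALSE,
                                   comment.char = "#"))
  storage.mode(m) <- "numeric"
  if (nrow(m) != ncol(m)) stop("scoring matrix must be square")
  m
}

#' Candidate matching blocks between two k-mer indices
#'
#' Performs a merged walk over the two sorted k-mer code vectors; every
#' shared k-mer yields a position pair, and runs of pairs on the same
#' diagonal are coalesced into contiguous blocks of matching positions.
#'
#' @param a,b `kmer_index` objects built with the same k and alphabet.
#' @return Integer matrix with columns `start1`, `start2` (0-based) and
#'   `length`.
#' @export
match_blocks <- function(a, b) {
  stopifnot(inherits(a, "kmer_index"), inherits(b, "kmer_index"),
            a$k == b$k)
  match_blocks_cpp(a$kmers, a$positions, b$kmers, b$positions, a$k)
}

#' Maximal collinear chain of matching blocks
#'
#' Selects, by dynamic programming, the subset of candidate blocks with
#' strictly increasing coordinates in both sequences that maximizes the
#' total number of anchored positions. Order-inconsistent matches are
#' thereby excluded. Ties are broken toward the chain whose first block
#' starts earlier in sequence 1, then toward fewer blocks.
#'
#' @param a,b `kmer_index` objects, or pass `candidates` directly.
#' @param candidates Optional precomputed block matrix (columns `start1`,
#'   `start2`, `length`) to chain instead of matching `a` and `b`.
#' @return A list of class `anchor_chain` with the kept `blocks` matrix and
#'   the total `anchored` positions.
#' @export
chain_blocks <- function(a = NULL, b = NULL, candidates = NULL) {
  if (is.null(candidates)) candidates <- match_blocks(a, b)
  out <- chain_blocks_cpp(candidates)
  structure(list(blocks = out$blocks, anchored = out$anchored),
            class = "anchor_chain")
}

#' @export
print.anchor_chain <- function(x, ...) {
  cat(sprintf("<anchor_chain> %d blocks, %g anchored positions\n",
              nrow(x$blocks), x$anchored))
  invisible(x)
}

#' Ordered-k-mer similarity from an anchor chain
#'
#' K-mer similarity is the number of anchored positions divided by the
#' estimated number of overlapping positions plus the minimum number of
#' implied gap runs (inter-anchor intervals whose flanking lengths differ
#' between the two sequences). The overlap is estimated from the first and
#' last anchor diagonals, clamped between the longest anchor and the
#' shorter sequence length. Under matching definitions this is a lower
#' bound on percent identity after alignment, because anchors are exact
#' matches and every unanchored position is counted against the numerator.
#'
#' @param chain An `anchor_chain` (or a block matrix).
#' @param len1,len2 The two sequence lengths.
#' @return A list with `similarity` and `coverage` (estimated overlap over
#'   the shorter length), both in `[0, 1]`.
#' @export
kmer_similarity <- function(chain, len1, len2) {
  blocks <- if (inherits(chain, "anchor_chain")) chain$blocks else chain
  v <- ksim_from_blocks_cpp(blocks, as.integer(len1), as.integer(len2))
  list(similarity = unname(v[1]), coverage = unname(v[2]))
}

#' Anchored affine-gap pairwise alignment
#'
#' Fixes the anchor chain as aligned columns and aligns each inter-anchor
#' region by global affine-gap dynamic programming; the two terminal
#' regions are aligned with free terminal gaps. With an empty chain this
#' reduces to a plain global alignment with free end gaps.
#'
#' @param seq1,seq2 Character sequences or 0-based integer code vectors.
#' @param chain An `anchor_chain` or block matrix (may have zero rows).
#' @param scoring A [scoring_scheme()].
#' @param alphabet Alphabet used to encode character input.
#' @return A list of class `alignment_result` with per-position accounting
#'   over the overlap region: `matches`, `mismatches`, `gap_runs`,
#'   `gap_positions`, `overlap_length`, the alignment `score`, the edit
#'   `ops` (0 aligned, 1 gap in seq1, 2 gap in seq2), and the two input
#'   lengths.
#' @export
anchored_align <- function(seq1, seq2, chain, scoring, alphabet = NULL) {
  if (is.character(seq1)) {
    stopifnot(!is.null(alphabet))
    seq1 <- alphabet$lookup[utf8ToInt(seq1) + 1L]
    seq2 <- alphabet$lookup[utf8ToInt(seq2) + 1L]
  }
  blocks <- if (inherits(chain, "anchor_chain")) chain$blocks else chain
  if (is.null(blocks)) blocks <- matrix(integer(0), 0, 3)
  out <- anchored_align_cpp(as.integer(seq1), as.integer(seq2), blocks,
                            unname(scoring$substitution),
                            scoring$gap_open, scoring$gap_extend)
  out$len1 <- length(seq1)
  out$len2 <- length(seq2)
  class(out) <- "alignment_result"
  out
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment_result> overlap %d: %d matches, %d mismatches, %d gap positions in %d runs (score %.1f)\n",
              x$overlap_length, x$matches, x$mismatches, x$gap_positions,
              x$gap_runs, x$score))
  invisible(x)
}

#' Percent identity and coverage of an alignment
#'
#' Computes identity under a [sim_config()]. With the default
#' overlap-region denominator: `matches / (matches + mismatches + G)` where
#' `G` is the number of gap runs (`one-mismatch-per-run`), the number of
#' gapped positions (`per-position-mismatch`), or zero (`ignore`). With the
#' shortest-sequence denominator the matches are divided by the shorter
#' sequence's length. Coverage is the aligned overlap length divided by the
#' shorter sequence's length; pairs with coverage below
#' `config$min_coverage` report `pass = FALSE`.
#'
#' @param aln An `alignment_result` (or any list with the same count
#'   fields plus `len1`/`len2`).
#' @param config A [sim_config()].
#' @return A list with `identity`, `coverage` and `pass`.
#' @export
percent_identity <- function(aln, config = sim_config()) {
  if (aln$overlap_length == 0L)
    return(list(identity = 0, coverage = 0, pass = FALSE))
  g <- switch(config$gap_mode,
              "one-mismatch-per-run" = aln$gap_runs,
              "per-position-mismatch" = aln$gap_positions,
              "ignore" = 0L)
  shorter <- min(aln$len1, aln$len2)
  denom <- switch(config$denominator,
                  "overlap-region" = aln$matches + aln$mismatches + g,
                  "shortest-sequence" = shorter + g)
  identity <- if (denom > 0) aln$matches / denom else 0
  coverage <- min(1, aln$overlap_length / shorter)
  list(identity = identity, coverage = coverage,
       pass = coverage >= config$min_coverage)
}

#' Aligned identity between two sequences
#'
#' Convenience wrapper running the full pairwise route: k-mer encoding,
#' block matching, collinear chaining, anchored alignment, and identity
#' under a [sim_config()].
#'
#' @param seq1,seq2 Character sequences.
#' @param k Matching k-mer length; defaults to a per-pair plan.
#' @param alphabet A [make_alphabet()] object or `NULL` to auto-detect.
#' @param config A [sim_config()].
#' @param scoring Optional [scoring_scheme()].
#' @return A list with `identity`, `coverage`, `pass`, `kmer_similarity`,
#'   and the underlying `alignment_result`.
#' @export
pair_similarity <- function(seq1, seq2, k = NULL, alphabet = NULL,
                            config = sim_config(), scoring = NULL) {
  if (is.null(alphabet))
    alphabet <- make_alphabet(detect_alphabet(c(seq1, seq2)))
  if (is.null(k))
    k <- choose_k_match(max(nchar(seq1), nchar(seq2)), alphabet$size)
  if (is.null(scoring)) scoring <- scoring_scheme(alphabet)
  i1 <- encode_kmers(seq1, k, alphabet)
  i2 <- encode_kmers(seq2, k, alphabet)
  ch <- chain_blocks(i1, i2)
  ks <- kmer_similarity(ch, nchar(seq1), nchar(seq2))
  aln <- anchored_align(seq1, seq2, ch, scoring, alphabet)
  pid <- percent_identity(aln, config)
  c(pid, list(kmer_similarity = ks$similarity, alignment = aln))
}
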