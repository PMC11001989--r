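#' Generate labeled synthetic sequence families
#'
#' Emulates sets of homologous sequence families for testing and
#' benchmarking clustering: each family has an independently drawn random
#' ancestor (so families are mutually unrelated, with expected identity at
#' the random-background level), and members are produced from the
#' ancestor by point substitutions at a controlled rate, indels with
#' geometric lengths, and optional partial-length truncation. The default
#' rates give members about 2% substitution divergence from their
#' ancestor, hence about 4% expected pairwise divergence within a family
#' - a recoverable design at a 0.9 similarity threshold.
#'
#' @param n_families Number of families G (default 10).
#' @param members Members per family (default 50). May be a vector of
#'   length `n_families`.
#' @param ancestor_length Ancestor length, a single value or a range
#'   `c(min, max)` sampled uniformly per family (default 300).
#' @param substitution_rate Per-position probability that a member differs
#'   from the ancestor by substitution, in `[0, 1)` (default 0.02).
#' @param indel_rate Per-position probability of an indel event (default
#'   0.001); each event inserts or deletes (equal odds) a stretch with
#'   geometric length of mean `indel_mean`.
#' @param indel_mean Mean indel length (default 2).
#' @param truncate_frac Fraction of members truncated to a partial length
#'   (default 0).
#' @param truncate_keep Range of the kept fraction for truncated members
#'   (default `c(0.6, 0.95)`); the kept side (prefix/suffix) is random.
#' @param alphabet `"DNA"` or `"AA"`.
#' @param root_divergence `NULL` (default) draws every family ancestor
#'   independently, making families mutually unrelated (random-background
#'   identity). A value in `(0, 1)` instead derives all family ancestors
#'   from one common root by substitutions at this rate, emulating a
#'   homologous low-diversity pool (one gene with many variant lineages,
#'   as in marker-gene or genome-surveillance collections) where families
#'   are distinguishable only at a high similarity threshold.
#' @param seed Optional integer seed; the output is byte-identical for
#'   the same seed.
#' @return A list with `sequences` (named character vector), `labels`
#'   (data frame `id`, `family`), `ancestors` (one per family), and the
#'   generation settings.
#' @examples
#' fam <- generate_families(n_families = 2, members = 3, seed = 1)
#' fam$labels
#' @export
generate_families <- function(n_families = 10L, members = 50L,
                              ancestor_length = 300L,
                              substitution_rate = 0.02,
                              indel_rate = 0.001, indel_mean = 2,
                              truncate_frac = 0,
                              truncate_keep = c(0.6, 0.95),
                              alphabet = c("DNA", "AA"),
                              root_divergence = NULL, seed = NULL) {
  alphabet <- match.arg(alphabet)
  stopifnot(n_families >= 1, all(members >= 1), all(ancestor_length >= 1))
  if (!is.numeric(substitution_rate) || substitution_rate < 0 ||
      substitution_rate >= 1)
    stop("'substitution_rate' must be in [0, 1)")
  if (indel_rate < 0 || indel_rate >= 1)
    stop("'indel_rate' must be in [0, 1)")
  if (truncate_frac < 0 || truncate_frac > 1)
    stop("'truncate_frac' must be in [0, 1]")
  if (!is.null(seed)) set.seed(as.integer(seed))
  letters <- make_alphabet(if (alphabet == "DNA") "DNA" else "AA")$letters
  x <- length(letters)
  if (length(members) == 1L) members <- rep(members, n_families)
  stopifnot(length(members) == n_families)
  if (!is.null(root_divergence) &&
      (root_divergence <= 0 || root_divergence >= 1))
    stop("'root_divergence' must be in (0, 1) or NULL")
  seqs <- character(sum(members))
  fam <- integer(sum(members))
  idx <- 0L
  root <- if (!is.null(root_divergence))
    sample.int(x, max(ancestor_length), replace = TRUE) else NULL
  ancestors <- character(n_families)
  for (f in seq_len(n_families)) {
    L <- if (length(ancestor_length) == 2L)
      sample(ancestor_length[1]:ancestor_length[2], 1L) else ancestor_length
    if (is.null(root)) {
      anc <- sample.int(x, L, replace = TRUE)
    } else {
      anc <- root[seq_len(L)]
      hit <- which(stats::runif(L) < root_divergence)
      if (length(hit) > 0L) {
        anc[hit] <- 1L + (anc[hit] - 1L +
                            sample.int(x - 1L, length(hit), replace = TRUE)) %% x
      }
    }
    ancestors[f] <- paste(letters[anc], collapse = "")
    for (m in seq_len(members[f])) {
      s <- anc
      # substitutions: shift to a uniformly chosen different letter
      hit <- which(stats::runif(length(s)) < substitution_rate)
      if (length(hit) > 0L) {
        s[hit] <- 1L + (s[hit] - 1L +
                          sample.int(x - 1L, length(hit), replace = TRUE)) %% x
      }
      # indel events with geometric lengths (mean indel_mean)
      nev <- stats::rbinom(1L, length(s), indel_rate)
      for (e in seq_len(nev)) {
        len <- stats::rgeom(1L, 1 / indel_mean) + 1L
        at <- sample.int(length(s), 1L)
        if (stats::runif(1) < 0.5) {
          ins <- sample.int(x, len, replace = TRUE)
          s <- append(s, ins, after = at)
        } else {
          drop <- at:min(length(s), at + len - 1L)
          if (length(drop) < length(s)) s <- s[-drop]
        }
      }
      # optional partial-length truncation
      if (truncate_frac > 0 && stats::runif(1) < truncate_frac) {
        keep <- stats::runif(1, truncate_keep[1], truncate_keep[2])
        nk <- max(1L, floor(keep * length(s)))
        s <- if (stats::runif(1) < 0.5) s[seq_len(nk)]
             else s[(length(s) - nk + 1L):length(s)]
      }
      idx <- idx + 1L
      seqs[idx] <- paste(letters[s], collapse = "")
      fam[idx] <- f
    }
  }
  ids <- sprintf("F%03d_M%03d", fam, unlist(lapply(members, seq_len)))
  names(seqs) <- ids
  list(sequences = seqs,
       labels = data.frame(id = ids, family = sprintf("F%03d", fam),
                           stringsAsFactors = FALSE),
       ancestors = stats::setNames(ancestors,
                                   sprintf("F%03d", seq_len(n_families))),
       settings = list(n_families = n_families, members = members,
                       ancestor_length = ancestor_length,
                       substitution_rate = substitution_rate,
                       indel_rate = indel_rate, indel_mean = indel_mean,
                       truncate_frac = truncate_frac, alphabet = alphabet,
                       root_divergence = root_divergence, seed = seed))
}
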