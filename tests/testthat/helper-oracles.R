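# Independent oracles and small fixture builders used across the suite.

rand_seq <- function(len, letters = c("A", "C", "G", "T")) {
  paste(sample(letters, len, replace = TRUE), collapse = "")
}

# mutate a sequence by point substitutions at the given rate
mutate_seq <- function(seq, rate, letters = c("A", "C", "G", "T")) {
  ch <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(ch)) < rate)
  for (i in hit) {
    ch[i] <- sample(setdiff(letters, ch[i]), 1L)
  }
  paste(ch, collapse = "")
}

# Exhaustive chain oracle: enumerates every strictly-increasing chain of
# candidate blocks and returns the maximum total anchored length.
oracle_chain_total <- function(blocks) {
  n <- nrow(blocks)
  if (n == 0L) return(0)
  ord <- order(blocks[, 1], blocks[, 2])
  b <- unname(blocks[ord, , drop = FALSE])
  storage.mode(b) <- "double"
  best <- 0
  recurse <- function(i, e1, e2, total) {
    if (total > best) best <<- total
    if (i > n) return(invisible())
    for (j in i:n) {
      if (b[j, 1] >= e1 && b[j, 2] >= e2) {
        recurse(j + 1L, b[j, 1] + b[j, 3], b[j, 2] + b[j, 3],
                total + b[j, 3])
      }
    }
  }
  recurse(1L, -Inf, -Inf, 0)
  best
}

# random candidate-block instances for the chain oracle
random_blocks <- function(n, span = 80L, max_len = 12L) {
  cbind(start1 = sample.int(span, n, replace = TRUE) - 1L,
        start2 = sample.int(span, n, replace = TRUE) - 1L,
        length = sample.int(max_len, n, replace = TRUE))
}

# Brute-force inverted index: bin -> sorted member ids
oracle_inverted_index <- function(selections) {
  out <- list()
  for (i in seq_along(selections)) {
    for (b in selections[[i]]) {
      key <- as.character(b)
      out[[key]] <- c(out[[key]], i)
    }
  }
  lapply(out, sort)
}

# group membership lookup through a rare_kmer_table
table_groups <- function(tb, i) {
  sl <- relclust:::rare_slots(tb, i)
  lapply(seq_along(sl$start), function(t)
    sort(tb$member[sl$start[t]:sl$end[t]]))
}

# encode + hash + select + table for a set of sequences (phase-1 plumbing)
build_rare_pipeline <- function(seqs, rare_per_seq = 50L) {
  ab <- make_alphabet("DNA")
  codes <- relclust:::encode_sequences(seqs, ab)
  plan <- kmer_plan(nchar(seqs), "DNA", rare_per_seq)
  bins <- lapply(codes, function(cv) {
    km <- relclust:::encode_kmers_cpp(cv, plan$k_rare, plan$x_rare)$kmers
    relclust:::hash_kmer_cpp(km, plan$s)
  })
  freq <- tabulate(unlist(bins) + 1L, nbins = plan$s)
  selections <- select_rare_kmers(bins, freq, rare_per_seq)
  list(plan = plan, bins = bins, freq = freq, selections = selections,
       table = build_rare_table(selections))
}

# aligned identity between two sequences via Biostrings (independent DP)
biostrings_overlap_score <- function(s1, s2, match = 3, transition = 0,
                                     transversion = -3,
                                     gap_open = 10, gap_extend = 2) {
  sub <- matrix(transversion, 4, 4,
                dimnames = list(c("A", "C", "G", "T"), c("A", "C", "G", "T")))
  diag(sub) <- match
  sub["A", "G"] <- sub["G", "A"] <- transition
  sub["C", "T"] <- sub["T", "C"] <- transition
  Biostrings::pairwiseAlignment(s1, s2, type = "overlap",
                                substitutionMatrix = sub,
                                gapOpening = gap_open,
                                gapExtension = gap_extend,
                                scoreOnly = TRUE)
}
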