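#' Residue alphabets
#'
#' Constructs one of the three alphabets used by the clustering pipeline:
#' the 4-letter nucleotide alphabet (`"DNA"`), the standard 20-letter
#' amino-acid alphabet (`"AA"`), or the reduced 10-letter amino-acid
#' alphabet (`"AA10"`) in which the groups (A,S,T), (R,K,Q), (N,D,E),
#' (I,V,L,M) and (F,Y) are merged and all other residues map to themselves.
#' The reduced alphabet is used for forming rare k-mers on proteins, where
#' tolerance to conservative substitutions is desirable; exact k-mer
#' matching always uses the full alphabet.
#'
#' Symbols outside the alphabet (ambiguity codes such as `N` or `X`, gap
#' characters, and anything non-standard) are not mapped: they encode as
#' `NA` and any k-mer window containing them is skipped.
#'
#' @param kind One of `"DNA"`, `"AA"`, `"AA10"`.
#' @return An object of class `seq_alphabet`: a list with elements
#'   `kind`, `letters` (ordered residue symbols), `size` (alphabet size x),
#'   and `lookup` (a 256-entry integer table from character codes to 0-based
#'   letter indices, `NA` for unmapped symbols).
#' @examples
#' a <- make_alphabet("AA10")
#' a$size  # 10
#' @export
make_alphabet <- function(kind = c("DNA", "AA", "AA10")) {
  kind <- match.arg(kind)
  if (kind == "DNA") {
    letters <- c("A", "C", "G", "T")
    groups <- as.list(letters)
  } else if (kind == "AA") {
    letters <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
    groups <- as.list(letters)
  } else {
    # merged groups, named by a representative residue
    groups <- list(c("A", "S", "T"), c("R", "K", "Q"), c("N", "D", "E"),
                   "C", "G", "H", c("I", "V", "L", "M"), c("F", "Y"),
                   "P", "W")
    letters <- vapply(groups, `[`, "", 1L)
  }
  lookup <- rep(NA_integer_, 256L)
  for (i in seq_along(groups)) {
    for (ch in groups[[i]]) {
      lookup[utf8ToInt(ch) + 1L] <- i - 1L
      lookup[utf8ToInt(tolower(ch)) + 1L] <- i - 1L
    }
  }
  if (kind == "DNA") {
    lookup[utf8ToInt("U") + 1L] <- lookup[utf8ToInt("T") + 1L]
    lookup[utf8ToInt("u") + 1L] <- lookup[utf8ToInt("T") + 1L]
  }
  structure(list(kind = kind, letters = letters, size = length(groups),
                 lookup = lookup),
            class = "seq_alphabet")
}

#' Reduce amino-acid residues to the 10-letter alphabet
#'
#' Maps each residue to the representative letter of its merged group:
#' A/S/T -> A, R/K/Q -> R, N/D/E -> N, I/V/L/M -> I, F/Y -> F; C, G, H, P
#' and W map to themselves. The mapping is idempotent. Unrecognized symbols
#' are returned as `NA`.
#'
#' @param x Character vector of single residues (case-insensitive).
#' @return Character vector of representative residues.
#' @examples
#' reduce_aa(c("S", "K", "V", "C", "Y"))  # "A" "R" "I" "C" "F"
#' @export
reduce_aa <- function(x) {
  a <- make_alphabet("AA10")
  idx <- a$lookup[utf8ToInt(paste(x, collapse = "")) + 1L]
  a$letters[idx + 1L]
}

#' @export
print.seq_alphabet <- function(x, ...) {
  cat(sprintf("<seq_alphabet> %s (%d letters): %s\n",
              x$kind, x$size, paste(x$letters, collapse = " ")))
  invisible(x)
}

#' Detect whether sequences are nucleotide or amino acid
#'
#' Classifies input as `"DNA"` when at least 95% of residues (sampled from
#' up to 100 sequences) are A, C, G, T, U or N, and `"AA"` otherwise.
#'
#' @param seqs Character vector of sequences.
#' @return `"DNA"` or `"AA"`.
#' @export
detect_alphabet <- function(seqs) {
  if (length(seqs) == 0L) return("DNA")
  take <- seqs[seq_len(min(100L, length(seqs)))]
  chars <- utf8ToInt(toupper(paste(take, collapse = "")))
  if (length(chars) == 0L) return("DNA")
  nuc <- utf8ToInt(paste(c("A", "C", "G", "T", "U", "N"), collapse = ""))
  if (mean(chars %in% nuc) >= 0.95) "DNA" else "AA"
}

# Encode character sequences as 0-based integer codes under an alphabet.
# Returns a list of integer vectors (NA for unmapped symbols).
encode_sequences <- function(seqs, alphabet) {
  lookup <- alphabet$lookup
  lapply(seqs, function(s) lookup[utf8ToInt(s) + 1L])
}
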