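#' Read sequences from a FASTA file
#'
#' Thin wrapper over `Biostrings::readBStringSet` (gzip-transparent).
#' FASTA description lines are truncated at the first whitespace to form
#' sequence ids.
#'
#' @param path Path to a FASTA file (optionally gzipped).
#' @return Named character vector of sequences.
#' @export
read_sequences <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read FASTA file '%s'", path))
  set <- Biostrings::readBStringSet(path)
  out <- as.character(set)
  names(out) <- sub("\\s.*$", "", names(set))
  out
}

#' Write a cluster assignment table
#'
#' Tab-separated table with columns `sequence_id`, `cluster_id`,
#' `is_representative` and `identity_to_representative`.
#'
#' @param object A [relclust()] object (or a compatible data frame).
#' @param path Output path.
#' @export
write_cluster_table <- function(object, path) {
  tab <- if (inherits(object, "relclust")) object$table else object
  out <- data.frame(sequence_id = tab$id, cluster_id = tab$cluster,
                    is_representative = tab$is_representative,
                    identity_to_representative =
                      round(tab$identity_to_representative, 6),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write cluster representative sequences as FASTA
#'
#' @param object A [relclust()] object.
#' @param path Output path.
#' @export
write_representatives <- function(object, path) {
  stopifnot(inherits(object, "relclust"))
  reps <- object$sequences[object$representatives]
  Biostrings::writeXStringSet(Biostrings::BStringSet(reps), path)
  invisible(path)
}

#' Read a sequence-id to label table
#'
#' Tab-separated file with two columns (`id`, `label`), with or without a
#' header line.
#'
#' @param path Path to the TSV file.
#' @return Named character vector of labels.
#' @export
read_labels <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (identical(tolower(df[1, 1]), "id")) df <- df[-1, , drop = FALSE]
  stats::setNames(as.character(df[[2]]), as.character(df[[1]]))
}
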