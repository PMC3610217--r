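#' Write a discriminative n-gram table as TSV
#'
#' Columns `gram`, `class`, `dr`, `n` in a fixed order: by class, then
#' descending DR, then alphabetically — so identical inputs always produce
#' byte-identical files.
#'
#' @param ngrams Tibble with at least columns `gram`, `class`, `dr`, `n`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ngram_table <- function(ngrams, path) {
  out <- dplyr::arrange(as_tibble(ngrams)[c("gram", "class", "dr", "n")],
                        .data$class, dplyr::desc(.data$dr), .data$gram)
  write_tsv_plain(out, path)
}

#' Read back a discriminative n-gram table
#'
#' @param path Path to a TSV written by [write_ngram_table()].
#' @return Tibble with columns `gram`, `class`, `dr`, `n`.
#' @export
read_ngram_table <- function(path) {
  out <- as_tibble(read.delim(path, colClasses = c(gram = "character",
                                                   class = "character",
                                                   dr = "numeric",
                                                   n = "integer")))
  out[c("gram", "class", "dr", "n")]
}

#' Write a motif interval table as TSV
#'
#' @param motifs Tibble with columns `seq_id`, `class`, `start`, `end`,
#'   `text`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_motif_table <- function(motifs, path) {
  cols <- c("seq_id", "class", "start", "end", "text")
  out <- dplyr::arrange(as_tibble(motifs)[cols], .data$seq_id, .data$start)
  write_tsv_plain(out, path)
}

write_tsv_plain <- function(x, path) {
  tryCatch(
    write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE),
    error = function(e) abort(paste0("cannot write ", path, ": ",
                                     conditionMessage(e))))
  invisible(path)
}
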