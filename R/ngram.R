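#' Extract all overlapping n-grams from a sequence
#'
#' Slides a window of width `n` across the sequence, yielding the
#' `max(0, k - n + 1)` overlapping substrings in left-to-right order for a
#' sequence of length `k`.
#'
#' @param residues A single sequence string.
#' @param n Window width (>= 1).
#' @return Character vector of n-grams; empty when the sequence is shorter
#'   than `n`.
#' @examples
#' extract_ngrams("MKVLA", 4)  # "MKVL" "KVLA"
#' @export
extract_ngrams <- function(residues, n) {
  stopifnot(length(residues) == 1, n >= 1)
  k <- nchar(residues)
  if (k < n) return(character())
  starts <- seq_len(k - n + 1L)
  stringi::stri_sub(residues, from = starts, length = n)
}

#' Build a per-class n-gram frequency profile
#'
#' Counts every overlapping occurrence of every n-gram in every sequence,
#' accumulated per class. Occurrences are counted individually (a gram
#' appearing twice in one sequence contributes 2), so per-class totals equal
#' the sum of `k_i - n + 1` over that class's sequences of length `k_i >= n`.
#'
#' @param data A sequence dataset (see [as_seq_dataset()]).
#' @param n n-gram size.
#' @return A tibble with column `gram` followed by one integer count column
#'   per class label (classes and grams in sorted order).
#' @export
ngram_profile <- function(data, n) {
  stopifnot(n >= 1)
  grams <- lapply(data$residues, extract_ngrams, n = n)
  long <- tibble(
    gram = unlist(grams, use.names = FALSE),
    class = rep(data$class, lengths(grams))
  )
  classes <- sort(unique(data$class))
  if (nrow(long) == 0) {
    out <- tibble(gram = character())
    for (cl in classes) out[[cl]] <- integer()
    return(out)
  }
  counts <- dplyr::count(long, .data$gram, .data$class)
  wide <- tidyr::pivot_wider(counts, names_from = "class", values_from = "n",
                             values_fill = 0L)
  for (cl in setdiff(classes, names(wide))) wide[[cl]] <- 0L
  wide <- wide[c("gram", classes)]
  dplyr::arrange(wide, .data$gram)
}

# Class-count columns of a profile-shaped tibble.
profile_classes <- function(profile) {
  setdiff(names(profile), c("gram", "presence", "damping"))
}

# Counts (or weights) of a profile-shaped tibble as a matrix.
profile_matrix <- function(profile) {
  cls <- profile_classes(profile)
  m <- as.matrix(profile[cls])
  rownames(m) <- profile$gram
  m
}

#' Number of classes each n-gram occurs in
#'
#' The presence count feeding the dampening factor: how many classes have a
#' raw (pre-substitution) occurrence count above zero.
#'
#' @param profile A raw profile from [ngram_profile()].
#' @return Integer vector aligned with `profile$gram`.
#' @export
presence_counts <- function(profile) {
  as.integer(rowSums(profile_matrix(profile) > 0))
}
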