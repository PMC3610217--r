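#' Remove n-grams that are substrings of longer n-grams
#'
#' Works on the pooled 4- to 8-gram set of one class: any gram contained in a
#' longer surviving gram is dropped, keeping the maximal strings. The
#' operation is idempotent and never removes a string of maximal length.
#'
#' @param grams Character vector of n-gram strings (mixed sizes allowed).
#' @return Character vector sorted alphabetically then by size, with no
#'   surviving string a substring of another.
#' @examples
#' remove_substrings(c("LMPQS", "SLMPQST"))  # "SLMPQST"
#' @export
remove_substrings <- function(grams) {
  grams <- unique(grams)
  if (length(grams) <= 1) return(grams)
  sizes <- nchar(grams)
  keep <- rep(TRUE, length(grams))
  for (s in sort(unique(sizes))) {
    longer <- grams[sizes > s]
    if (length(longer) == 0) next
    haystack <- paste(longer, collapse = "\x01")
    at_s <- which(sizes == s)
    hit <- stringi::stri_detect_fixed(haystack, grams[at_s])
    keep[at_s[hit]] <- FALSE
  }
  out <- grams[keep]
  out[order(out, nchar(out))]
}

#' Map discriminative n-grams onto their class's sequences
#'
#' Locates every occurrence of every discriminative n-gram in the sequences
#' of its assigned class (and only that class), as 1-based inclusive
#' intervals. Per-sequence hits are sorted by start position, with equal
#' starts ordered by descending end so the longest hit anchors a later merge.
#'
#' @param data A sequence dataset.
#' @param ngrams Tibble with columns `gram` and `class` (e.g. output of
#'   [score_ngrams()] after [remove_substrings()]).
#' @return Tibble of hits: `seq_id`, `class`, `start`, `end`, `text`.
#' @export
map_ngrams <- function(data, ngrams) {
  cols <- c("seq_id", "class", "start", "end", "text")
  pieces <- lapply(split(ngrams$gram, ngrams$class), unique)
  out <- purrr::imap(pieces, function(grams, cl) {
    seqs <- data[data$class == cl, ]
    if (nrow(seqs) == 0 || length(grams) == 0) return(NULL)
    hits <- purrr::map(grams, function(g) {
      loc <- stringi::stri_locate_all_fixed(seqs$residues, g, overlap = TRUE)
      nhit <- vapply(loc, function(m) sum(!is.na(m[, 1])), integer(1))
      if (sum(nhit) == 0) return(NULL)
      m <- do.call(rbind, loc)
      ok <- !is.na(m[, 1])
      tibble(seq_id = rep(seqs$seq_id, nhit),
             class = cl, start = m[ok, 1], end = m[ok, 2], text = g)
    })
    dplyr::bind_rows(hits)
  })
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0) {
    return(tibble(seq_id = character(), class = character(),
                  start = integer(), end = integer(), text = character()))
  }
  dplyr::arrange(out[cols], .data$seq_id, .data$start, dplyr::desc(.data$end))
}

#' Merge contiguous and overlapping n-gram hits into motifs
#'
#' Sweeps each sequence's sorted hit list left to right, merging a hit into
#' the growing motif whenever its start is at most one past the current end
#' (overlapping, abutting, or separated by no gap). Chains merge transitively
#' to a fixed point; surviving motifs are pairwise separated by a gap of at
#' least 2 (end < next start - 1).
#'
#' @param hits Hit tibble from [map_ngrams()].
#' @param data The sequence dataset (to recover each merged motif's text).
#' @return Motif tibble: `seq_id`, `class`, `start`, `end`, `text`.
#' @export
merge_intervals <- function(hits, data) {
  if (nrow(hits) == 0) return(hits)
  hits <- dplyr::arrange(hits, .data$seq_id, .data$start, dplyr::desc(.data$end))
  merged <- dplyr::group_modify(dplyr::group_by(hits, .data$seq_id, .data$class),
                                function(h, key) {
    starts <- h$start
    ends <- h$end
    # new motif starts where a hit begins beyond current-end + 1
    run_end <- cummax(ends)
    breaks <- c(TRUE, starts[-1] > run_end[-length(run_end)] + 1L)
    grp <- cumsum(breaks)
    idx <- split(seq_along(starts), grp)  # numeric factor levels sort numerically
    tibble(start = vapply(idx, function(j) min(starts[j]), numeric(1)),
           end = vapply(idx, function(j) max(ends[j]), numeric(1)))
  })
  merged <- dplyr::ungroup(merged)
  merged$start <- as.integer(merged$start)
  merged$end <- as.integer(merged$end)
  merged$text <- stringi::stri_sub(
    data$residues[match(merged$seq_id, data$seq_id)],
    merged$start, merged$end)
  dplyr::arrange(merged[c("seq_id", "class", "start", "end", "text")],
                 .data$seq_id, .data$start)
}

#' Mask the non-discriminative regions of sequences
#'
#' Replaces every residue not covered by a motif interval with `X`, keeping
#' covered residues untouched, so downstream pattern matching only sees the
#' discriminative regions. Intervals on one sequence must be non-overlapping
#' (merge them first); sequences with no motif become all-`X`.
#'
#' @param data A sequence dataset.
#' @param motifs Motif tibble from [merge_intervals()] (columns `seq_id`,
#'   `start`, `end`).
#' @return The dataset tibble with an added `masked` column.
#' @export
mask_sequences <- function(data, motifs) {
  by_seq <- split(motifs, motifs$seq_id)
  masked <- vapply(seq_len(nrow(data)), function(i) {
    res <- data$residues[i]
    iv <- by_seq[[data$seq_id[i]]]
    if (is.null(iv) || nrow(iv) == 0) {
      return(strrep("X", nchar(res)))
    }
    iv <- iv[order(iv$start), ]
    if (any(iv$start < 1 | iv$end > nchar(res) | iv$start > iv$end)) {
      abort(paste0("interval out of bounds on ", data$seq_id[i]))
    }
    if (nrow(iv) > 1 && any(iv$start[-1] <= iv$end[-nrow(iv)])) {
      abort(paste0("overlapping intervals on ", data$seq_id[i],
                   "; merge them first"))
    }
    out <- strrep("X", nchar(res))
    for (j in seq_len(nrow(iv))) {
      stringi::stri_sub(out, iv$start[j], iv$end[j]) <-
        stringi::stri_sub(res, iv$start[j], iv$end[j])
    }
    out
  }, character(1))
  out <- data
  out$masked <- masked
  out
}
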