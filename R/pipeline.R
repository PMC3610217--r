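#' Run the full discriminative-motif discovery pipeline
#'
#' Executes, in order, for each n-gram size: extraction, substitution
#' enrichment, dampening, discriminative-ratio selection and cross-class
#' deduplication; then pools all sizes, removes substring n-grams per class,
#' maps the survivors onto their class's sequences, merges contiguous and
#' overlapping hits into motifs, and (optionally) masks the
#' non-discriminative regions. The pipeline is fully deterministic.
#'
#' @param data A sequence dataset (see [as_seq_dataset()]).
#' @param n_min,n_max Range of n-gram sizes (default 4..8; larger sizes cost
#'   exponentially more and are warned about).
#' @param threshold Selection threshold T (> 1); n-grams with DR >= T are
#'   kept.
#' @param substitution Combine BLOSUM-positive single-substitution variants
#'   (SF1, default) or score exact n-grams only (SF2).
#' @param blosum_threshold Minimum substitution score for similarity
#'   (default 1).
#' @param mask Also produce masked sequences (default TRUE).
#' @param matrix Substitution matrix (default the embedded BLOSUM62).
#' @return An object of class `motif_discovery`: a list with tibbles
#'   `ngrams` (gram, n, class, dr, seed, display), `motifs` (seq_id, class,
#'   start, end, text), `masked` (when requested), per-stage `counts`, and
#'   the `config` used.
#' @examples
#' sim <- simulate_dataset(seed = 42)
#' disc <- discover_motifs(sim$data, n_min = 8, n_max = 8, threshold = 5)
#' glance(disc)
#' @export
discover_motifs <- function(data, n_min = 4L, n_max = 8L, threshold = 5,
                            substitution = TRUE, blosum_threshold = 1L,
                            mask = TRUE, matrix = load_blosum62()) {
  stopifnot(n_min >= 1, n_max >= n_min)
  if (n_max > 8) {
    warn("n-gram sizes beyond 8 grow exponentially costly; proceeding anyway")
  }
  data <- as_seq_dataset(data)
  per_size <- lapply(seq(n_min, n_max), function(n) {
    score_ngrams(data, n, threshold = threshold, substitution = substitution,
                 blosum_threshold = blosum_threshold, matrix = matrix)
  })
  pooled <- dplyr::bind_rows(per_size)
  n_selected <- nrow(pooled)

  # substring removal on the pooled multi-size set, within each class
  filtered <- dplyr::group_modify(
    dplyr::group_by(pooled, .data$class),
    function(g, key) g[g$gram %in% remove_substrings(g$gram), ])
  filtered <- dplyr::ungroup(filtered)
  filtered <- dplyr::arrange(
    filtered[c("gram", "n", "class", "dr", "seed", "display")],
    .data$class, dplyr::desc(.data$dr), .data$gram)

  hits <- map_ngrams(data, filtered)
  motifs <- merge_intervals(hits, data)
  masked <- if (mask) mask_sequences(data, motifs) else NULL

  counts <- tibble(stage = c("selected", "after_substring_removal",
                             "mapped_hits", "merged_motifs"),
                   count = c(n_selected, nrow(filtered), nrow(hits),
                             nrow(motifs)))
  structure(list(ngrams = filtered, motifs = motifs, masked = masked,
                 counts = counts,
                 config = list(n_min = n_min, n_max = n_max,
                               threshold = threshold,
                               substitution = substitution,
                               blosum_threshold = blosum_threshold,
                               mask = mask,
                               classes = sort(unique(data$class)),
                               n_sequences = nrow(data))),
            class = "motif_discovery")
}

#' @export
print.motif_discovery <- function(x, ...) {
  cfg <- x$config
  cat("Discriminative n-gram discovery (",
      if (cfg$substitution) "SF1, with substitution" else "SF2, no substitution",
      ")\n", sep = "")
  cat("  sizes ", cfg$n_min, "..", cfg$n_max, ", threshold T = ",
      cfg$threshold, ", ", length(cfg$classes), " classes, ",
      cfg$n_sequences, " sequences\n", sep = "")
  cat("  ", nrow(x$ngrams), " discriminative n-grams -> ", nrow(x$motifs),
      " merged motifs\n", sep = "")
  invisible(x)
}

#' Tidy the discriminative n-gram table of a discovery run
#'
#' @param x A `motif_discovery` object.
#' @param ... Unused.
#' @return The n-gram tibble (`gram`, `n`, `class`, `dr`, `seed`, `display`).
#' @export
tidy.motif_discovery <- function(x, ...) x$ngrams

#' One-row summary of a discovery run
#'
#' @param x A `motif_discovery` object.
#' @param ... Unused.
#' @return A one-row tibble with run settings and stage counts.
#' @export
glance.motif_discovery <- function(x, ...) {
  tibble(n_classes = length(x$config$classes),
         n_sequences = x$config$n_sequences,
         n_min = x$config$n_min, n_max = x$config$n_max,
         threshold = x$config$threshold,
         substitution = x$config$substitution,
         n_ngrams = nrow(x$ngrams),
         n_motifs = nrow(x$motifs),
         median_dr = stats::median(x$ngrams$dr))
}
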