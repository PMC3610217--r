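#' Find the BLOSUM-positive single-substitution neighbors of an n-gram
#'
#' Returns every n-gram present in `grams` that differs from `seed` at exactly
#' one position, where the pair of differing residues scores at or above
#' `blosum_threshold` in the substitution matrix. Only n-grams actually
#' observed in the data qualify — never the full combinatorial neighborhood.
#'
#' @param seed An n-gram string.
#' @param grams Character vector of observed n-grams (e.g. `profile$gram`).
#' @param matrix A substitution matrix (see [load_blosum62()]).
#' @param blosum_threshold Minimum score for the differing residue pair
#'   (default 1, i.e. any positive BLOSUM62 score).
#' @return Sorted character vector of neighbors; never contains `seed`.
#' @examples
#' blosum_neighbors("TLSNPK", c("TLNNPK", "TLSDPK", "TLSSPK", "QQQQQQ"))
#' @export
blosum_neighbors <- function(seed, grams, matrix = load_blosum62(),
                             blosum_threshold = 1L) {
  n <- nchar(seed)
  variants <- character()
  for (i in seq_len(n)) {
    alpha <- substr(seed, i, i)
    for (beta in positive_partners(alpha, matrix, blosum_threshold)) {
      v <- seed
      substr(v, i, i) <- beta
      variants <- c(variants, v)
    }
  }
  sort(intersect(variants, grams))
}

#' Combine an n-gram with its similar neighbors
#'
#' Pools a seed n-gram with its single-position BLOSUM-positive variants into
#' a combined n-gram: per-position residue sets, a bracket display string
#' (e.g. `TL[SN][NDS]PK`), and class-wise summed occurrence counts over seed
#' plus constituents.
#'
#' @param seed The seed n-gram.
#' @param similars Character vector of neighbors from [blosum_neighbors()].
#' @param profile The raw frequency profile holding counts for seed and
#'   neighbors.
#' @return A list with elements `seed`, `constituents`, `position_sets`,
#'   `display` and `counts` (named per-class integer vector).
#' @export
combine_ngrams <- function(seed, similars, profile) {
  members <- c(seed, sort(setdiff(similars, seed)))
  idx <- match(members, profile$gram)
  if (anyNA(idx)) {
    abort(paste0("gram(s) absent from profile: ",
                 paste(members[is.na(idx)], collapse = ", ")))
  }
  n <- nchar(seed)
  position_sets <- lapply(seq_len(n), function(i) {
    unique(substr(members, i, i))  # first-seen order, seed residue first
  })
  display <- paste(vapply(position_sets, function(s) {
    if (length(s) == 1) s else paste0("[", paste(s, collapse = ""), "]")
  }, character(1)), collapse = "")
  m <- profile_matrix(profile)[idx, , drop = FALSE]
  list(seed = seed,
       constituents = members,
       position_sets = position_sets,
       display = display,
       counts = colSums(m))
}

#' Enrich a frequency profile by substitution combining
#'
#' For every n-gram (taken as the seed of its own group) adds the raw counts
#' of all its single-position, BLOSUM-positive neighbors present in the
#' profile, class-wise. Groups are seed-centric and may overlap; they are
#' never merged transitively. With `substitution = FALSE` the profile is
#' returned unchanged (the no-substitution variant of the scoring function,
#' SF2).
#'
#' @inheritParams blosum_neighbors
#' @param profile A raw profile from [ngram_profile()].
#' @param substitution Apply combining (TRUE, SF1) or not (FALSE, SF2).
#' @return A profile-shaped tibble of enriched counts.
#' @export
enrich_profile <- function(profile, matrix = load_blosum62(),
                           blosum_threshold = 1L, substitution = TRUE) {
  if (!substitution || nrow(profile) == 0) return(profile)
  grams <- profile$gram
  n <- unique(nchar(grams))
  if (length(n) != 1) abort("profile must hold n-grams of a single size")
  counts <- profile_matrix(profile)
  enriched <- counts
  for (i in seq_len(n)) {
    d <- tibble(
      idx = seq_along(grams),
      key = paste(stringi::stri_sub(grams, 1L, i - 1L),
                  stringi::stri_sub(grams, i + 1L, n), sep = "\x01"),
      res = stringi::stri_sub(grams, i, i)
    )
    pairs <- dplyr::inner_join(d, d, by = "key", suffix = c("", "_other"),
                               relationship = "many-to-many")
    pairs <- pairs[pairs$idx != pairs$idx_other &
                     matrix[cbind(pairs$res, pairs$res_other)] >= blosum_threshold, ]
    if (nrow(pairs) > 0) {
      add <- rowsum(counts[pairs$idx_other, , drop = FALSE], pairs$idx)
      target <- as.integer(rownames(add))
      enriched[target, ] <- enriched[target, , drop = FALSE] + add
    }
  }
  out <- profile
  out[profile_classes(profile)] <- as_tibble(enriched)
  out
}
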