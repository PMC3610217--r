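#' Dampening factor for class presence
#'
#' TF-IDF-style weight `ln(|C| / (k - 0.1))` for an n-gram present in `k` of
#' `|C|` classes. The 0.1 denominator adjustment keeps the factor strictly
#' positive even for grams present in every class (where `ln(|C|/|C|)` would
#' vanish), and is applied uniformly so the factor stays strictly decreasing
#' in `k`.
#'
#' @param num_classes Total number of classes, `|C|` (>= 2).
#' @param presence_count Number of classes the gram occurs in, in
#'   `1..num_classes`. Vectorized.
#' @return Numeric vector of dampening factors, all positive.
#' @examples
#' damping_factor(10, 1)   # ~2.408: class-exclusive grams get the largest boost
#' damping_factor(10, 10)  # ~0.01: ubiquitous grams are almost silenced
#' @export
damping_factor <- function(num_classes, presence_count) {
  if (num_classes < 2) abort("damping needs at least 2 classes")
  if (any(presence_count < 1 | presence_count > num_classes)) {
    abort("presence_count must lie in 1..num_classes")
  }
  log(num_classes / (presence_count - 0.1))
}

#' Dampen an enriched profile across unbalanced classes
#'
#' Multiplies each n-gram's per-class (enriched) counts by its dampening
#' factor. The presence count is taken from the RAW profile — the number of
#' classes where the gram itself occurs, before substitution pooling.
#'
#' @param enriched Enriched profile from [enrich_profile()].
#' @param presence Integer vector of raw class-presence counts, aligned with
#'   `enriched$gram` (see [presence_counts()]).
#' @return A tibble with columns `gram`, `presence`, `damping`, then one
#'   numeric weight column per class.
#' @export
dampen_profile <- function(enriched, presence) {
  cls <- profile_classes(enriched)
  if (length(presence) != nrow(enriched)) {
    abort("presence vector must align with the profile rows")
  }
  fac <- damping_factor(length(cls), presence)
  out <- tibble(gram = enriched$gram, presence = as.integer(presence),
                damping = fac)
  w <- profile_matrix(enriched) * fac
  out[cls] <- as_tibble(w)
  out
}

#' Discriminative ratio of a per-class weight vector
#'
#' The ratio of the highest dampened class weight to the mean of the second
#' and third highest, with three degenerate-case substitutions applied in
#' order: if the second and third highest are both zero the mean is taken as
#' 1; if only the third is zero the mean is taken as the second highest; and
#' if the resulting mean falls strictly between 0 and 1 it is floored to 1.
#'
#' @param weights Named numeric vector of per-class dampened weights
#'   (length >= 3; the statistic is undefined for two classes).
#' @return A list with `dr` (the ratio) and `top_class` (the argmax label,
#'   `NA` when the maximum is tied across classes).
#' @examples
#' discriminative_ratio(c(A = 7, B = 0, C = 0))    # dr = 7
#' discriminative_ratio(c(A = 12, B = 4, C = 0))   # dr = 3
#' discriminative_ratio(c(A = 5, B = 0.6, C = 0.2))  # dr = 5
#' @export
discriminative_ratio <- function(weights) {
  if (length(weights) < 3) {
    abort("the discriminative ratio needs at least 3 classes")
  }
  if (is.null(names(weights))) names(weights) <- as.character(seq_along(weights))
  res <- dr_matrix(matrix(weights, nrow = 1,
                          dimnames = list(NULL, names(weights))))
  list(dr = res$dr, top_class = res$class)
}

# Vectorized DR over a weight matrix (rows = grams, cols = classes).
# Returns tibble(dr, class, tie).
dr_matrix <- function(w) {
  if (ncol(w) < 3) {
    abort(paste0("the discriminative ratio is undefined for ", ncol(w),
                 " classes; provide at least 3"))
  }
  top_idx <- max.col(w, ties.method = "first")
  n <- nrow(w)
  w1 <- w[cbind(seq_len(n), top_idx)]
  tie <- rowSums(w == w1) > 1
  w2m <- w
  w2m[cbind(seq_len(n), top_idx)] <- -Inf
  second_idx <- max.col(w2m, ties.method = "first")
  w2 <- w2m[cbind(seq_len(n), second_idx)]
  w2m[cbind(seq_len(n), second_idx)] <- -Inf
  w3 <- w2m[cbind(seq_len(n), max.col(w2m, ties.method = "first"))]
  mean23 <- (w2 + w3) / 2
  mean23[w2 == 0 & w3 == 0] <- 1                  # both zero -> 1
  only3 <- w3 == 0 & w2 > 0
  mean23[only3] <- w2[only3]                      # third zero -> second
  mean23[mean23 > 0 & mean23 < 1] <- 1            # fractional mean -> 1
  tibble(dr = unname(w1 / mean23),
         class = unname(ifelse(tie, NA_character_, colnames(w)[top_idx])),
         tie = unname(tie))
}

#' Select discriminative n-grams from a dampened profile
#'
#' Keeps every n-gram whose discriminative ratio meets the selection
#' threshold, assigned to its highest-weight class. When a raw profile and
#' substitution settings are supplied (SF1), each qualifying seed also emits
#' all constituents of its combined n-gram as discriminative, carrying the
#' combined gram's DR, class and display string. Grams whose top weight is
#' tied across classes are never selected.
#'
#' @param damped Dampened profile from [dampen_profile()].
#' @param threshold Selection threshold T (> 1); grams with `dr >= threshold`
#'   are kept.
#' @param profile Raw profile (needed to expand constituents under SF1).
#' @param matrix,blosum_threshold Substitution settings, as in
#'   [enrich_profile()].
#' @param substitution Expand constituents (SF1) or not (SF2).
#' @return A tibble with columns `gram`, `n`, `class`, `dr`, `seed`,
#'   `display`. May contain one gram several times (from different seeds);
#'   see [dedupe_ngrams()].
#' @export
select_discriminative <- function(damped, threshold, profile = NULL,
                                  matrix = load_blosum62(),
                                  blosum_threshold = 1L, substitution = TRUE) {
  if (threshold <= 1) abort("selection threshold must exceed 1")
  cls <- profile_classes(damped)
  empty <- tibble(gram = character(), n = integer(), class = character(),
                  dr = numeric(), seed = character(), display = character())
  if (nrow(damped) == 0) return(empty)
  res <- dr_matrix(profile_matrix(damped))
  keep <- !res$tie & res$dr >= threshold
  if (!any(keep)) return(empty)
  seeds <- tibble(gram = damped$gram[keep], class = res$class[keep],
                  dr = res$dr[keep])
  if (substitution && !is.null(profile)) {
    rows <- purrr::pmap(seeds, function(gram, class, dr) {
      seed_gram <- gram
      nb <- blosum_neighbors(seed_gram, profile$gram, matrix, blosum_threshold)
      cmb <- combine_ngrams(seed_gram, nb, profile)
      tibble(gram = cmb$constituents, n = nchar(seed_gram), class = class,
             dr = dr, seed = seed_gram, display = cmb$display)
    })
    out <- dplyr::bind_rows(rows)
  } else {
    out <- tibble(gram = seeds$gram, n = nchar(seeds$gram), class = seeds$class,
                  dr = seeds$dr, seed = seeds$gram, display = seeds$gram)
  }
  dplyr::arrange(out, .data$class, dplyr::desc(.data$dr), .data$gram)
}

#' Deduplicate discriminative n-grams across classes
#'
#' A gram may qualify in several classes (or via several seeds) with
#' different DRs; only the record with the highest DR survives. Ties go to
#' the lexicographically smaller class label, then the lexicographically
#' smaller seed.
#'
#' @param items Tibble of discriminative n-grams from
#'   [select_discriminative()].
#' @return Tibble with each gram appearing exactly once, ordered by class,
#'   descending DR, then gram.
#' @export
dedupe_ngrams <- function(items) {
  if (nrow(items) == 0) return(items)
  out <- dplyr::arrange(items, .data$gram, dplyr::desc(.data$dr),
                        .data$class, .data$seed)
  out <- dplyr::distinct(out, .data$gram, .keep_all = TRUE)
  dplyr::arrange(out, .data$class, dplyr::desc(.data$dr), .data$gram)
}

#' Score one n-gram size end to end
#'
#' Runs extraction, substitution enrichment, dampening, DR computation,
#' selection and cross-class deduplication for a single n-gram size.
#'
#' @param data A sequence dataset (see [as_seq_dataset()]).
#' @param n n-gram size.
#' @param threshold Selection threshold T (> 1).
#' @param substitution Combine BLOSUM-positive neighbors (SF1, default) or
#'   score exact grams only (SF2).
#' @param blosum_threshold Minimum substitution score for similarity.
#' @param matrix Substitution matrix.
#' @return Tibble of discriminative n-grams (`gram`, `n`, `class`, `dr`,
#'   `seed`, `display`), one row per gram.
#' @examples
#' data <- simulate_dataset(seed = 7)$data
#' score_ngrams(data, n = 8, threshold = 5)
#' @export
score_ngrams <- function(data, n, threshold = 5, substitution = TRUE,
                         blosum_threshold = 1L, matrix = load_blosum62()) {
  profile <- ngram_profile(data, n)
  check_min_classes(profile)
  enriched <- enrich_profile(profile, matrix, blosum_threshold, substitution)
  damped <- dampen_profile(enriched, presence_counts(profile))
  sel <- select_discriminative(damped, threshold, profile = profile,
                               matrix = matrix,
                               blosum_threshold = blosum_threshold,
                               substitution = substitution)
  dedupe_ngrams(sel)
}

check_min_classes <- function(profile) {
  k <- length(profile_classes(profile))
  if (k < 3) {
    abort(paste0("found ", k, " class(es); the discriminative ratio needs ",
                 "at least 3 (its denominator averages the 2nd and 3rd ",
                 "highest class frequencies)"))
  }
  invisible(profile)
}
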