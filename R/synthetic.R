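#' Simulate a class-labeled dataset with planted class-specific motifs
#'
#' Generates random protein sequences in several (possibly unbalanced)
#' classes and plants class-exclusive motifs into a fixed fraction of each
#' class's sequences. A planted instance optionally carries one
#' BLOSUM62-positive single-residue substitution, emulating point-mutation
#' variants of a conserved signal. Motif strings are globally unique, never
#' substrings of one another, and rejection sampling guarantees no motif
#' appears in another class's sequences.
#'
#' @param num_classes Number of classes (>= 3).
#' @param seqs_per_class Integer vector of class sizes (recycled to
#'   `num_classes`); unbalanced sizes are the interesting case.
#' @param seq_length Sequence length (single integer, or length-2 range
#'   sampled uniformly).
#' @param motifs_per_class Planted motifs per class.
#' @param motif_length Motif length (single integer, or length-2 range).
#' @param plant_rate Fraction of a class's sequences carrying each motif.
#' @param mutation_rate Probability a planted instance carries one
#'   BLOSUM62-positive single-residue substitution.
#' @param background `"uniform"` over the 20 residues, or `"natural"`
#'   (approximate vertebrate amino-acid frequencies).
#' @param blosum_threshold Minimum substitution score for a mutation to be
#'   considered conservative.
#' @param seed Integer seed; the same seed reproduces the dataset exactly.
#' @return A list with `data` (a sequence dataset tibble) and `truth`
#'   (list of `motifs`: tibble `class`, `motif`; and `intervals`: tibble
#'   `seq_id`, `class`, `motif`, `start`, `end`, `text`, `mutated`).
#' @examples
#' sim <- simulate_dataset(seed = 42)
#' dplyr::count(sim$data, class)
#' @export
simulate_dataset <- function(num_classes = 5L,
                             seqs_per_class = c(30L, 50L, 80L, 120L, 200L),
                             seq_length = 300L,
                             motifs_per_class = 2L,
                             motif_length = c(6L, 12L),
                             plant_rate = 0.6,
                             mutation_rate = 0.3,
                             background = c("uniform", "natural"),
                             blosum_threshold = 1L,
                             seed = 1L) {
  stopifnot(num_classes >= 3, motifs_per_class >= 0,
            plant_rate >= 0, plant_rate <= 1,
            mutation_rate >= 0, mutation_rate <= 1)
  background <- match.arg(background)
  sizes <- rep_len(as.integer(seqs_per_class), num_classes)
  withr::local_seed(seed)
  probs <- if (background == "uniform") rep(1 / 20, 20) else natural_freqs()
  matrix <- load_blosum62()
  classes <- sprintf("C%02d", seq_len(num_classes))

  # class-exclusive motifs: globally unique, no motif a substring of another
  motifs <- character(0)
  truth_motifs <- NULL
  for (cl in classes) {
    for (m in seq_len(motifs_per_class)) {
      for (try in 1:100) {
        len <- sample_scalar(motif_length)
        cand <- paste(sample(AA_ALPHABET, len, replace = TRUE, prob = probs),
                      collapse = "")
        clash <- any(stringi::stri_detect_fixed(motifs, cand)) ||
          any(stringi::stri_detect_fixed(cand, motifs))
        if (!clash) break
        if (try == 100) abort("could not draw non-overlapping motif strings")
      }
      motifs <- c(motifs, cand)
      truth_motifs <- rbind(truth_motifs,
                            data.frame(class = cl, motif = cand))
    }
  }
  truth_motifs <- as_tibble(truth_motifs %||% data.frame(class = character(),
                                                         motif = character()))

  records <- vector("list", sum(sizes))
  intervals <- list()
  r <- 0
  for (ci in seq_along(classes)) {
    cl <- classes[ci]
    own <- truth_motifs$motif[truth_motifs$class == cl]
    foreign <- setdiff(motifs, own)
    carriers <- lapply(own, function(m) {
      sample(seq_len(sizes[ci]), size = round(plant_rate * sizes[ci]))
    })
    for (si in seq_len(sizes[ci])) {
      r <- r + 1
      id <- sprintf("%s_seq%03d", cl, si)
      plant <- own[vapply(carriers, function(cs) si %in% cs, logical(1))]
      ok <- FALSE
      for (try in 1:100) {
        len <- sample_scalar(seq_length)
        res <- paste(sample(AA_ALPHABET, len, replace = TRUE, prob = probs),
                     collapse = "")
        planted <- plant_motifs(res, plant, mutation_rate, matrix,
                                blosum_threshold)
        if (is.null(planted)) next  # could not place without overlap
        # exclusivity: no foreign motif may appear, planted or by chance
        if (length(foreign) > 0 &&
            any(stringi::stri_detect_fixed(planted$res, foreign))) next
        ok <- TRUE
        break
      }
      if (!ok) abort("could not generate a motif-exclusive sequence")
      records[[r]] <- tibble(seq_id = id, class = cl, residues = planted$res)
      if (nrow(planted$iv) > 0) {
        planted$iv$seq_id <- id
        planted$iv$class <- cl
        intervals[[length(intervals) + 1]] <- planted$iv
      }
    }
  }
  data <- dplyr::bind_rows(records)
  iv <- if (length(intervals) > 0) dplyr::bind_rows(intervals) else
    tibble(motif = character(), start = integer(), end = integer(),
           text = character(), mutated = logical(),
           seq_id = character(), class = character())
  iv <- iv[c("seq_id", "class", "motif", "start", "end", "text", "mutated")]
  list(data = as_seq_dataset(data),
       truth = list(motifs = truth_motifs,
                    intervals = dplyr::arrange(iv, .data$seq_id, .data$start)))
}

sample_scalar <- function(x) {
  if (length(x) == 1) as.integer(x) else sample(seq(x[1], x[2]), 1)
}

# Approximate vertebrate amino-acid background frequencies.
natural_freqs <- function() {
  f <- c(A = 7.4, C = 3.3, D = 5.9, E = 5.8, F = 4.0, G = 7.4, H = 2.9,
         I = 3.8, K = 7.2, L = 7.6, M = 1.8, N = 4.4, P = 5.0, Q = 3.7,
         R = 4.2, S = 8.1, T = 6.2, V = 6.8, W = 1.3, Y = 3.3)
  unname(f[AA_ALPHABET] / sum(f))
}

# Plant motif instances at non-overlapping positions; returns NULL when no
# non-overlapping placement was found.
plant_motifs <- function(res, plant, mutation_rate, matrix, blosum_threshold) {
  iv <- tibble(motif = character(), start = integer(), end = integer(),
               text = character(), mutated = logical())
  if (length(plant) == 0) return(list(res = res, iv = iv))
  k <- nchar(res)
  occupied <- integer(0)
  for (m in plant) {
    len <- nchar(m)
    placed <- FALSE
    for (try in 1:50) {
      s <- sample(seq_len(k - len + 1), 1)
      span <- s:(s + len - 1)
      if (length(intersect(span, occupied)) > 0) next
      inst <- m
      mutated <- FALSE
      if (stats::runif(1) < mutation_rate) {
        inst <- mutate_one(m, matrix, blosum_threshold)
        mutated <- inst != m
      }
      stringi::stri_sub(res, s, s + len - 1) <- inst
      occupied <- c(occupied, span)
      iv <- dplyr::bind_rows(iv, tibble(motif = m, start = s,
                                        end = s + len - 1L, text = inst,
                                        mutated = mutated))
      placed <- TRUE
      break
    }
    if (!placed) return(NULL)
  }
  list(res = res, iv = iv)
}

# One conservative substitution at a random position that has a
# BLOSUM-positive partner; residues without one (C, G, P) are skipped.
mutate_one <- function(motif, matrix, blosum_threshold) {
  pos <- sample(nchar(motif))
  for (i in pos) {
    partners <- positive_partners(substr(motif, i, i), matrix, blosum_threshold)
    if (length(partners) > 0) {
      out <- motif
      substr(out, i, i) <- sample(partners, 1)
      return(out)
    }
  }
  motif
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Score motif recovery against the planted ground truth
#'
#' A planted motif counts as recovered when at least one discriminative
#' n-gram of the correct class occurs entirely inside one of that motif's
#' planted intervals. A discriminative n-gram counts as background when every
#' one of its occurrences in its assigned class's sequences lies completely
#' outside (disjoint from) all planted intervals — grams straddling a motif
#' boundary are signal, not background; grams occurring nowhere also count as
#' background.
#'
#' @param ngrams Tibble of discriminative n-grams (`gram`, `class`).
#' @param truth The `truth` element of [simulate_dataset()].
#' @param data The simulated dataset the grams were mined from.
#' @return List of class `recovery_report`: `summary` (one-row tibble with
#'   `recall`, `background_rate`, `n_motifs`, `n_recovered`, `n_ngrams`,
#'   `n_background`) and `by_class` (the same per class).
#' @export
score_recovery <- function(ngrams, truth, data) {
  iv <- truth$intervals
  motifs <- truth$motifs
  per_gram_inside <- rep(FALSE, nrow(ngrams))  # overlaps some planted interval
  hit_motif <- setNames(rep(FALSE, nrow(motifs)),
                        paste(motifs$class, motifs$motif))
  if (nrow(ngrams) > 0) {
    for (g in seq_len(nrow(ngrams))) {
      cl <- ngrams$class[g]
      seqs <- data[data$class == cl, ]
      loc <- stringi::stri_locate_all_fixed(seqs$residues, ngrams$gram[g],
                                            overlap = TRUE)
      inside <- FALSE
      for (si in seq_len(nrow(seqs))) {
        m <- loc[[si]]
        if (is.na(m[1, 1])) next
        here <- iv[iv$seq_id == seqs$seq_id[si], ]
        if (nrow(here) == 0) next
        for (hi in seq_len(nrow(m))) {
          # full containment recovers the motif; any overlap disqualifies
          # the gram from being a background discovery
          cover <- m[hi, 1] >= here$start & m[hi, 2] <= here$end
          overlap <- m[hi, 1] <= here$end & m[hi, 2] >= here$start
          if (any(overlap)) inside <- TRUE
          if (any(cover)) hit_motif[paste(cl, here$motif[cover])] <- TRUE
        }
      }
      per_gram_inside[g] <- inside
    }
  }
  motifs$recovered <- unname(hit_motif[paste(motifs$class, motifs$motif)])
  by_class <- dplyr::summarise(
    dplyr::group_by(motifs, .data$class),
    n_motifs = dplyr::n(), n_recovered = sum(.data$recovered),
    recall = mean(.data$recovered), .groups = "drop")
  bg <- dplyr::summarise(
    dplyr::group_by(tibble(class = ngrams$class, inside = per_gram_inside),
                    .data$class),
    n_ngrams = dplyr::n(), n_background = sum(!.data$inside),
    background_rate = mean(!.data$inside), .groups = "drop")
  by_class <- dplyr::left_join(by_class, bg, by = "class")
  summary <- tibble(
    recall = mean(motifs$recovered),
    background_rate = if (nrow(ngrams) > 0) mean(!per_gram_inside) else NA_real_,
    n_motifs = nrow(motifs), n_recovered = sum(motifs$recovered),
    n_ngrams = nrow(ngrams), n_background = sum(!per_gram_inside))
  structure(list(summary = summary, by_class = by_class),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("Motif recovery:", x$summary$n_recovered, "of", x$summary$n_motifs,
      "planted motifs (recall", format(x$summary$recall, digits = 3),
      "); background rate",
      format(x$summary$background_rate, digits = 3), "over",
      x$summary$n_ngrams, "discriminative n-grams\n")
  invisible(x)
}

#' @export
glance.recovery_report <- function(x, ...) x$summary

#' @export
tidy.recovery_report <- function(x, ...) x$by_class
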