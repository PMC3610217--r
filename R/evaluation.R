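#' Confusion matrix of discriminative n-grams against a dataset
#'
#' Each discriminative n-gram assigned to class `c` contributes one count to
#' cell `[c', c]` for every class `c'` in whose sequences it occurs at least
#' once (rows = class of occurrence, columns = assigned class). Diagonal
#' entries are true positives; a row sum minus its diagonal gives the false
#' negatives of that class, a column sum minus its diagonal the false
#' positives, and the remaining mass the true negatives. Grams occurring in
#' no sequence at all are tallied separately and counted as false negatives
#' of their assigned class.
#'
#' @param ngrams Tibble with columns `gram` and `class`.
#' @param data The evaluation dataset (training set or a mapped-domain
#'   subset).
#' @return An integer matrix of class `ngram_confusion` with an `unmapped`
#'   attribute (named per-class counts of grams found nowhere).
#' @export
ngram_confusion <- function(ngrams, data) {
  classes <- sort(unique(data$class))
  cm <- matrix(0L, length(classes), length(classes),
               dimnames = list(occurred = classes, assigned = classes))
  unmapped <- setNames(integer(length(classes)), classes)
  if (nrow(ngrams) > 0) {
    bad <- setdiff(ngrams$class, classes)
    if (length(bad) > 0) {
      abort(paste0("assigned class absent from dataset: ",
                   paste(bad, collapse = ", ")))
    }
    haystacks <- vapply(classes, function(cl) {
      paste(data$residues[data$class == cl], collapse = "\x01")
    }, character(1))
    occ <- vapply(classes, function(cl) {
      stringi::stri_detect_fixed(haystacks[[cl]], ngrams$gram)
    }, logical(nrow(ngrams)))
    occ <- matrix(occ, nrow = nrow(ngrams), dimnames = list(NULL, classes))
    for (j in seq_along(classes)) {
      rows <- occ[ngrams$class == classes[j], , drop = FALSE]
      cm[, j] <- colSums(rows)
      unmapped[j] <- sum(rowSums(rows) == 0)
    }
  }
  structure(cm, unmapped = unmapped, class = c("ngram_confusion", "matrix"))
}

cm_counts <- function(cm) {
  m <- unclass(cm)
  attr(m, "unmapped") <- NULL
  tp <- diag(m)
  fn <- rowSums(m) - tp + attr(cm, "unmapped")
  fp <- colSums(m) - tp
  tn <- sum(m) - tp - (rowSums(m) - tp) - fp
  tibble(class = colnames(m), tp = as.integer(tp), fn = as.integer(fn),
         fp = as.integer(fp), tn = as.integer(tn))
}

#' Per-class sensitivity and specificity
#'
#' Sensitivity is TP / (TP + FN), specificity TN / (TN + FP). Zero
#' denominators yield `NA`, never a coerced 0.
#'
#' @param cm An [ngram_confusion()] matrix.
#' @param class Optional single class label; when omitted, all classes.
#' @return With `class`: a single number. Without: a tibble with columns
#'   `class`, `tp`, `fn`, `fp`, `tn`, `sensitivity`, `specificity`.
#' @export
class_metrics <- function(cm, class = NULL) {
  tab <- cm_counts(cm)
  tab$sensitivity <- ifelse(tab$tp + tab$fn > 0, tab$tp / (tab$tp + tab$fn), NA_real_)
  tab$specificity <- ifelse(tab$tn + tab$fp > 0, tab$tn / (tab$tn + tab$fp), NA_real_)
  if (is.null(class)) return(tab)
  tab[tab$class == class, ]
}

#' @rdname class_metrics
#' @export
sensitivity <- function(cm, class = NULL) {
  tab <- class_metrics(cm, class)
  setNames(tab$sensitivity, tab$class)
}

#' @rdname class_metrics
#' @export
specificity <- function(cm, class = NULL) {
  tab <- class_metrics(cm, class)
  setNames(tab$specificity, tab$class)
}

#' @export
tidy.ngram_confusion <- function(x, ...) {
  m <- unclass(x)
  attr(m, "unmapped") <- NULL
  out <- as_tibble(as.table(m), .name_repair = "minimal")
  names(out) <- c("occurred", "assigned", "count")
  out$count <- as.integer(out$count)
  out
}

#' ROC curve and trapezoidal AUC from operating points
#'
#' Builds a ROC curve from (FPR, TPR) operating points — typically one per
#' selection threshold — anchored at (0,0) and (1,1), and integrates the
#' area under it with the trapezoidal rule.
#'
#' @param points Tibble (or data frame) with columns `fpr` and `tpr`; a
#'   `threshold` column, if present, is carried through.
#' @return A list of class `roc_curve` with elements `points` (sorted, with
#'   anchors) and `auc`.
#' @examples
#' roc_curve(tibble::tibble(fpr = 0, tpr = 1))$auc   # 1: perfect
#' roc_curve(tibble::tibble(fpr = 0.5, tpr = 0.5))$auc  # 0.5: chance
#' @export
roc_curve <- function(points) {
  points <- as_tibble(points)
  if (nrow(points) == 0) abort("need at least one operating point")
  if (!all(c("fpr", "tpr") %in% names(points))) {
    abort("points need columns `fpr` and `tpr`")
  }
  if (any(points$fpr < 0 | points$fpr > 1 | points$tpr < 0 | points$tpr > 1,
          na.rm = TRUE)) {
    abort("rates must lie in [0, 1]")
  }
  pts <- points[stats::complete.cases(points[c("fpr", "tpr")]), ]
  anchors <- tibble(fpr = c(0, 1), tpr = c(0, 1))
  all_pts <- dplyr::bind_rows(pts[intersect(names(pts), c("threshold", "fpr", "tpr"))],
                              anchors)
  all_pts <- dplyr::arrange(all_pts, .data$fpr, .data$tpr)
  auc <- trapezoid_auc(all_pts$fpr, all_pts$tpr)
  structure(list(points = all_pts, auc = auc), class = "roc_curve")
}

trapezoid_auc <- function(x, y) {
  sum(diff(x) * (head(y, -1) + y[-1]) / 2)
}

#' @export
print.roc_curve <- function(x, ...) {
  cat("ROC curve:", nrow(x$points), "points (incl. anchors), AUC =",
      format(x$auc, digits = 4), "\n")
  invisible(x)
}

#' @export
glance.roc_curve <- function(x, ...) {
  tibble(n_points = nrow(x$points), auc = x$auc)
}

#' @export
tidy.roc_curve <- function(x, ...) x$points

#' Sweep the selection threshold and collect per-class operating points
#'
#' Scores the dataset once per n-gram size, then re-selects at each
#' threshold, pools sizes, and evaluates a confusion matrix against
#' `eval_data`, yielding one (FPR, TPR) point per class and threshold. The
#' dampened profiles are computed once; only selection is repeated.
#'
#' @param data Training dataset.
#' @param thresholds Numeric vector of selection thresholds (all > 1).
#' @param eval_data Dataset to evaluate occurrences against (defaults to
#'   `data`).
#' @inheritParams discover_motifs
#' @return Tibble with columns `threshold`, `class`, `tp`, `fn`, `fp`, `tn`,
#'   `sensitivity`, `specificity`, `tpr`, `fpr`.
#' @export
sweep_thresholds <- function(data, thresholds = 5:10, eval_data = data,
                             n_min = 4L, n_max = 8L, substitution = TRUE,
                             blosum_threshold = 1L, matrix = load_blosum62()) {
  stopifnot(all(thresholds > 1))
  staged <- lapply(seq(n_min, n_max), function(n) {
    profile <- ngram_profile(data, n)
    check_min_classes(profile)
    enriched <- enrich_profile(profile, matrix, blosum_threshold, substitution)
    list(profile = profile,
         damped = dampen_profile(enriched, presence_counts(profile)))
  })
  rows <- lapply(thresholds, function(th) {
    pooled <- dplyr::bind_rows(lapply(staged, function(s) {
      dedupe_ngrams(select_discriminative(
        s$damped, th, profile = s$profile, matrix = matrix,
        blosum_threshold = blosum_threshold, substitution = substitution))
    }))
    cm <- ngram_confusion(pooled, eval_data)
    out <- class_metrics(cm)
    out$threshold <- th
    out
  })
  out <- dplyr::bind_rows(rows)
  out$tpr <- out$sensitivity
  out$fpr <- 1 - out$specificity
  out[c("threshold", "class", "tp", "fn", "fp", "tn",
        "sensitivity", "specificity", "tpr", "fpr")]
}
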