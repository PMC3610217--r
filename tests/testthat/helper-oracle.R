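# Independent straight-line reference implementation of the discovery
# scoring path (counting -> substitution pooling -> dampening -> DR ->
# selection -> constituent emission -> cross-class dedupe), written with
# plain loops and a named-list accumulator so it shares no code with the
# package internals it checks.

oracle_discover <- function(data, n, threshold, substitution = TRUE,
                            blosum_threshold = 1, matrix = NULL) {
  if (is.null(matrix)) matrix <- motifgram::load_blosum62()
  classes <- sort(unique(data$class))
  counts <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(data))) {
    s <- data$residues[i]
    cl <- data$class[i]
    k <- nchar(s)
    if (k < n) next
    for (p in seq_len(k - n + 1)) {
      g <- substr(s, p, p + n - 1)
      cur <- if (is.null(counts[[g]])) {
        stats::setNames(numeric(length(classes)), classes)
      } else counts[[g]]
      cur[cl] <- cur[cl] + 1
      counts[[g]] <- cur
    }
  }
  grams <- ls(counts)
  present_neighbors <- function(g) {
    out <- character(0)
    for (p in seq_len(n)) {
      a <- substr(g, p, p)
      for (b in rownames(matrix)) {
        if (b != a && matrix[a, b] >= blosum_threshold) {
          v <- g
          substr(v, p, p) <- b
          if (!is.null(counts[[v]])) out <- c(out, v)
        }
      }
    }
    sort(unique(out))
  }
  rows <- list()
  for (g in grams) {
    raw <- counts[[g]]
    nb <- if (substitution) present_neighbors(g) else character(0)
    enr <- raw
    for (v in nb) enr <- enr + counts[[v]]
    k_pres <- sum(raw > 0)
    w <- enr * log(length(classes) / (k_pres - 0.1))
    o <- sort(w, decreasing = TRUE)
    if (sum(w == o[1]) > 1) next  # tied top class: never discriminative
    m <- (o[2] + o[3]) / 2
    if (o[2] == 0 && o[3] == 0) {
      m <- 1
    } else if (o[3] == 0) {
      m <- o[2]
    }
    if (m > 0 && m < 1) m <- 1
    dr <- o[1] / m
    if (dr >= threshold) {
      top <- names(w)[which.max(w)]
      for (member in c(g, nb)) {
        rows[[length(rows) + 1]] <- data.frame(
          gram = member, class = top, dr = dr, seed = g,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(gram = character(), class = character(),
                          dr = numeric()))
  }
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$gram, -tab$dr, tab$class, tab$seed), ]
  tab <- tab[!duplicated(tab$gram), ]
  tab <- tab[order(tab$class, -tab$dr, tab$gram), c("gram", "class", "dr")]
  rownames(tab) <- NULL
  tibble::as_tibble(tab)
}

# Small random datasets over a reduced alphabet (so grams recur and
# substitution neighborhoods are non-trivial).
toy_dataset <- function(seed, num_classes = 3, max_seqs = 12, max_len = 40) {
  set.seed(seed)
  alphabet <- c("A", "C", "D", "E", "F", "G", "S", "T", "N", "K")
  rows <- list()
  id <- 0
  for (cl in paste0("K", seq_len(num_classes))) {
    for (s in seq_len(sample(3:max_seqs, 1))) {
      id <- id + 1
      len <- sample(10:max_len, 1)
      rows[[id]] <- tibble::tibble(
        seq_id = sprintf("s%03d", id), class = cl,
        residues = paste(sample(alphabet, len, replace = TRUE), collapse = ""))
    }
  }
  dplyr::bind_rows(rows)
}

# Toy profile tibble built by hand (gram + per-class counts).
toy_profile <- function(grams, ...) {
  out <- tibble::tibble(gram = grams)
  cols <- list(...)
  for (nm in names(cols)) out[[nm]] <- as.integer(cols[[nm]])
  out
}
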