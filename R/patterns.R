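#' Convert an NLSdb- or PROSITE-dialect pattern to a regular expression
#'
#' Both dialects describe linear protein motifs but not in regex syntax.
#' NLSdb patterns use literal residues with `x` wildcards and `{a,b}` repeat
#' counts (`KKPx{6,9}Kx{1,3}RK`). PROSITE patterns separate elements with
#' `-`, use `x` wildcards, `(a)`/`(a,b)` repeats, `[..]` residue choices,
#' `{..}` residue exclusions and `<`/`>` terminal anchors
#' (`G-S-x(2)-M-x-{RS}-K-x-N`). Already-converted regex patterns pass through
#' unchanged.
#'
#' @param raw Pattern string in the declared dialect.
#' @param dialect One of `"prosite"`, `"nlsdb"`, `"regex"`.
#' @return A one-row tibble with columns `raw`, `dialect`, `converted`.
#' @examples
#' convert_pattern("KKPx{6,9}Kx{1,3}RK", "nlsdb")$converted
#' convert_pattern("G-S-x(2)-M-x-{RS}-K-x-N", "prosite")$converted
#' @export
convert_pattern <- function(raw, dialect = c("prosite", "nlsdb", "regex")) {
  dialect <- match.arg(tolower(dialect), c("prosite", "nlsdb", "regex"))
  if (length(raw) != 1 || !nzchar(raw)) abort("pattern must be a single non-empty string")
  converted <- switch(dialect,
                      regex = raw,
                      nlsdb = convert_nlsdb(raw),
                      prosite = convert_prosite(raw))
  ok <- tryCatch(suppressWarnings({ regexpr(converted, "", perl = TRUE); TRUE }),
                 error = function(e) FALSE)
  if (!ok) abort(paste0("converted pattern does not compile: ", converted))
  tibble(raw = raw, dialect = dialect, converted = converted)
}

convert_nlsdb <- function(raw) {
  chars <- strsplit(raw, "", fixed = TRUE)[[1]]
  out <- character(0)
  i <- 1
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "x") {
      out <- c(out, ".")
      i <- i + 1
    } else if (grepl("[A-Z]", ch)) {
      out <- c(out, ch)
      i <- i + 1
    } else if (ch == "{") {
      j <- match("}", chars[i:length(chars)])
      if (is.na(j)) abort(paste0("unclosed '{' at offset ", i, " in ", raw))
      body <- paste(chars[(i + 1):(i + j - 2)], collapse = "")
      if (!grepl("^[0-9]+(,[0-9]+)?$", body)) {
        abort(paste0("bad repeat '{", body, "}' at offset ", i, " in ", raw))
      }
      out <- c(out, "{", body, "}")
      i <- i + j
    } else {
      abort(paste0("unparseable token '", ch, "' at offset ", i, " in ", raw))
    }
  }
  paste(out, collapse = "")
}

convert_prosite <- function(raw) {
  pat <- sub("\\.$", "", raw)  # PROSITE entries end with '.'
  anchored_start <- startsWith(pat, "<")
  anchored_end <- endsWith(pat, ">")
  if (anchored_start) pat <- substr(pat, 2, nchar(pat))
  if (anchored_end) pat <- substr(pat, 1, nchar(pat) - 1)
  elements <- strsplit(pat, "-", fixed = TRUE)[[1]]
  out <- vapply(seq_along(elements), function(k) {
    el <- elements[k]
    m <- regmatches(el, regexec(
      "^(x|[A-Z]|\\[[A-Z]+\\]|\\{[A-Z]+\\})(\\(([0-9]+)(,([0-9]+))?\\))?$", el))[[1]]
    if (length(m) == 0) {
      abort(paste0("unparseable PROSITE element '", el, "' (element ", k,
                   ") in ", raw))
    }
    core <- m[2]
    core <- if (core == "x") {
      "."
    } else if (startsWith(core, "{")) {
      paste0("[^", substr(core, 2, nchar(core) - 1), "]")
    } else {
      core
    }
    rep <- ""
    if (nzchar(m[3])) {
      rep <- if (nzchar(m[5])) paste0("{", m[4], ",", m[6], "}")
             else paste0("{", m[4], "}")
    }
    paste0(core, rep)
  }, character(1))
  paste0(if (anchored_start) "^" else "", paste(out, collapse = ""),
         if (anchored_end) "$" else "")
}

#' Match a pattern against subject strings
#'
#' Unanchored search (unless the pattern itself carries `^`/`$`) of a
#' converted pattern against each subject, reporting the first match span in
#' 1-based inclusive coordinates. By default the `.` wildcard may match the
#' `X` of masked sequences; with `wildcard_matches_mask = FALSE` wildcards
#' are restricted to real residues.
#'
#' @param pattern A tibble from [convert_pattern()], or a plain regex string.
#' @param subjects Character vector of subject sequences (raw or masked).
#' @param wildcard_matches_mask Should `.` match the mask character `X`?
#' @return Tibble with columns `subject`, `matched`, `start`, `end`, `match`.
#' @export
match_pattern <- function(pattern, subjects, wildcard_matches_mask = TRUE) {
  rx <- if (is.data.frame(pattern)) pattern$converted[1] else pattern
  if (!wildcard_matches_mask) rx <- exclude_mask_from_wildcards(rx)
  m <- regexpr(rx, subjects, perl = TRUE)
  start <- as.integer(ifelse(m > 0, m, NA))
  len <- attr(m, "match.length")
  end <- as.integer(ifelse(m > 0, start + len - 1L, NA))
  tibble(subject = subjects, matched = m > 0, start = start, end = end,
         match = ifelse(m > 0, substr(subjects, start, end), NA_character_))
}

# '.' outside character classes -> [^X]; inside [...] left alone.
exclude_mask_from_wildcards <- function(rx) {
  chars <- strsplit(rx, "", fixed = TRUE)[[1]]
  depth <- 0
  out <- vapply(chars, function(ch) {
    if (ch == "[") depth <<- depth + 1
    if (ch == "]") depth <<- max(0, depth - 1)
    if (ch == "." && depth == 0) "[^X]" else ch
  }, character(1))
  paste(out, collapse = "")
}

#' Fraction of subjects matched by at least one pattern
#'
#' Coverage of a class: the ratio of sequences in which a pattern match was
#' found to the total number of sequences, counting each subject once however
#' many patterns hit it.
#'
#' @param patterns A tibble of converted patterns ([convert_pattern()] rows
#'   bound together), or a character vector of regexes.
#' @param subjects Character vector of subject sequences (non-empty).
#' @param wildcard_matches_mask Passed to [match_pattern()].
#' @return A single number in `[0, 1]`.
#' @export
pattern_coverage <- function(patterns, subjects, wildcard_matches_mask = TRUE) {
  if (length(subjects) == 0) abort("coverage over zero subjects is undefined")
  rxs <- if (is.data.frame(patterns)) patterns$converted else patterns
  if (length(rxs) == 0) return(0)
  hit <- rep(FALSE, length(subjects))
  for (rx in rxs) {
    hit <- hit | match_pattern(rx, subjects, wildcard_matches_mask)$matched
  }
  mean(hit)
}

#' Per-pattern match counts across subjects
#'
#' Companion to [pattern_coverage()]: how many subjects each individual
#' pattern hits.
#'
#' @inheritParams pattern_coverage
#' @return Tibble with columns `pattern` (converted regex) and `n_matched`.
#' @export
pattern_matches <- function(patterns, subjects, wildcard_matches_mask = TRUE) {
  rxs <- if (is.data.frame(patterns)) patterns$converted else patterns
  tibble(pattern = rxs,
         n_matched = vapply(rxs, function(rx) {
           sum(match_pattern(rx, subjects, wildcard_matches_mask)$matched)
         }, integer(1), USE.NAMES = FALSE))
}

#' Read a pattern list file
#'
#' One pattern per line; blank lines and `#` comments are skipped. All
#' patterns in one file share a dialect.
#'
#' @param path Path to the pattern file.
#' @param dialect Dialect of every pattern in the file.
#' @return Tibble of converted patterns, one row each.
#' @export
read_patterns <- function(path, dialect = c("prosite", "nlsdb", "regex")) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  dplyr::bind_rows(lapply(lines, convert_pattern, dialect = dialect))
}
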