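test_that("substring removal keeps maximal strings only", {
  expect_equal(remove_substrings(c("LMPQS", "SLMPQST")), "SLMPQST")
  expect_setequal(remove_substrings(c("AAAA", "CCCC")), c("AAAA", "CCCC"))
  pool <- c("GSSIM", "SSIM", "GSSIMP", "KKPR", "AAAA")
  once <- remove_substrings(pool)
  expect_setequal(once, c("GSSIMP", "KKPR", "AAAA"))
  expect_equal(remove_substrings(once), once)  # idempotent
  # never removes a string of maximal length; output is a subset of input
  set.seed(5)
  rand <- unique(replicate(30, paste(sample(c("A", "C", "G"), sample(4:8, 1),
                                            replace = TRUE), collapse = "")))
  out <- remove_substrings(rand)
  expect_true(all(out %in% rand))
  expect_true(all(rand[nchar(rand) == max(nchar(rand))] %in% out))
})

test_that("mapping locates every occurrence as 1-based inclusive intervals", {
  data <- tibble::tibble(seq_id = c("s1", "s2"), class = "A",
                         residues = c("XXGSSIMYY", "GSSIMAAGSSIM"))
  hits <- map_ngrams(data, tibble::tibble(gram = "GSSIM", class = "A"))
  expect_equal(hits$start[hits$seq_id == "s1"], 3)
  expect_equal(hits$end[hits$seq_id == "s1"], 7)
  expect_equal(nrow(hits[hits$seq_id == "s2", ]), 2)
  expect_equal(hits$text, rep("GSSIM", 3))
  # grams are mapped only onto their own class's sequences
  data2 <- rbind(data, tibble::tibble(seq_id = "s3", class = "B",
                                      residues = "GSSIMGSSIM"))
  hits2 <- map_ngrams(data2, tibble::tibble(gram = "GSSIM", class = "A"))
  expect_false("s3" %in% hits2$seq_id)
})

test_that("mapped intervals equal a brute-force all-positions scan", {
  data <- toy_dataset(51, max_seqs = 4, max_len = 25)
  grams <- unique(unlist(lapply(data$residues, extract_ngrams, n = 4)))[1:15]
  ngrams <- tibble::tibble(gram = grams,
                           class = sample(unique(data$class), 15, replace = TRUE))
  hits <- map_ngrams(data, ngrams)
  ref <- list()
  for (gi in seq_len(nrow(ngrams))) {
    seqs <- data[data$class == ngrams$class[gi], ]
    g <- ngrams$gram[gi]
    for (si in seq_len(nrow(seqs))) {
      s <- seqs$residues[si]
      for (p in seq_len(nchar(s) - nchar(g) + 1)) {
        if (substr(s, p, p + nchar(g) - 1) == g) {
          ref[[length(ref) + 1]] <- tibble::tibble(
            seq_id = seqs$seq_id[si], class = ngrams$class[gi],
            start = p, end = p + nchar(g) - 1L, text = g)
        }
      }
    }
  }
  ref <- dplyr::arrange(dplyr::bind_rows(ref), seq_id, start, dplyr::desc(end), text)
  got <- dplyr::arrange(hits, seq_id, start, dplyr::desc(end), text)
  got$start <- as.integer(got$start)
  got$end <- as.integer(got$end)
  expect_equal(got, ref)
})

test_that("the merge rule joins hits with end >= next start - 1, transitively", {
  data <- tibble::tibble(seq_id = "s1", class = "A",
                         residues = paste(rep("ACDEFGHIKL", 3), collapse = ""))
  mk <- function(s, e) tibble::tibble(seq_id = "s1", class = "A",
                                      start = s, end = e,
                                      text = substr(data$residues[1], s, e))
  # end exactly one less than the next start: merge
  m <- merge_intervals(rbind(mk(3, 8), mk(9, 12)), data)
  expect_equal(c(m$start, m$end), c(3, 12))
  # overlap: merge
  m <- merge_intervals(rbind(mk(3, 8), mk(6, 12)), data)
  expect_equal(c(m$start, m$end), c(3, 12))
  # gap of 2: stays split
  m <- merge_intervals(rbind(mk(3, 8), mk(11, 14)), data)
  expect_equal(m$start, c(3, 11))
  # chains resolve to a fixed point
  m <- merge_intervals(rbind(mk(1, 5), mk(5, 9), mk(10, 14)), data)
  expect_equal(c(m$start, m$end), c(1, 14))
  # nested interval swallowed regardless of input order
  m <- merge_intervals(rbind(mk(5, 7), mk(3, 12)), data)
  expect_equal(c(m$start, m$end), c(3, 12))
  # output pairwise satisfies end < next start - 1 and text matches the slice
  m <- merge_intervals(rbind(mk(1, 4), mk(8, 10), mk(9, 14), mk(20, 22)), data)
  expect_true(all(m$end[-nrow(m)] < m$start[-1] - 1))
  expect_equal(m$text, substring(data$residues[1], m$start, m$end))
})

test_that("merging preserves the union of covered positions", {
  data <- toy_dataset(52, max_seqs = 3, max_len = 30)
  grams <- unique(unlist(lapply(data$residues, extract_ngrams, n = 4)))
  ngrams <- tidyr::expand_grid(gram = grams[1:20],
                               class = unique(data$class))
  hits <- map_ngrams(data, ngrams)
  motifs <- merge_intervals(hits, data)
  for (id in unique(hits$seq_id)) {
    h <- hits[hits$seq_id == id, ]
    m <- motifs[motifs$seq_id == id, ]
    cover_in <- unique(unlist(mapply(seq, h$start, h$end, SIMPLIFY = FALSE)))
    cover_out <- unlist(mapply(seq, m$start, m$end, SIMPLIFY = FALSE))
    expect_equal(sort(cover_in), sort(cover_out))
    expect_equal(anyDuplicated(cover_out), 0)
  }
})

test_that("masking flips uncovered positions to X and preserves the rest", {
  data <- tibble::tibble(seq_id = "s1", class = "A", residues = "PENEPGSSIM")
  motifs <- tibble::tibble(seq_id = "s1", class = "A", start = 6L, end = 10L,
                           text = "GSSIM")
  out <- mask_sequences(data, motifs)
  expect_equal(out$masked, "XXXXXGSSIM")
  # no motifs: fully masked, same length
  none <- mask_sequences(data, motifs[0, ])
  expect_equal(none$masked, strrep("X", 10))
  # motif spanning the whole sequence: identity
  whole <- mask_sequences(data, tibble::tibble(seq_id = "s1", class = "A",
                                               start = 1L, end = 10L,
                                               text = data$residues))
  expect_equal(whole$masked, data$residues)
  # overlapping intervals must be merged first
  overlap <- tibble::tibble(seq_id = "s1", class = "A",
                            start = c(2L, 4L), end = c(5L, 8L),
                            text = c("ENEP", "EPGSS"))
  expect_error(mask_sequences(data, overlap), "merge")
  # out-of-bounds interval rejected
  oob <- tibble::tibble(seq_id = "s1", class = "A", start = 8L, end = 12L,
                        text = "SIM")
  expect_error(mask_sequences(data, oob), "bounds")
})

test_that("masking preserves coordinates on arbitrary merged motifs", {
  data <- toy_dataset(53, max_seqs = 3, max_len = 30)
  grams <- unique(unlist(lapply(data$residues, extract_ngrams, n = 5)))
  ngrams <- tidyr::expand_grid(gram = grams[1:10], class = unique(data$class))
  motifs <- merge_intervals(map_ngrams(data, ngrams), data)
  out <- mask_sequences(data, motifs)
  expect_equal(nchar(out$masked), nchar(data$residues))
  for (i in seq_len(nrow(out))) {
    chars_m <- strsplit(out$masked[i], "")[[1]]
    chars_r <- strsplit(out$residues[i], "")[[1]]
    keep <- chars_m != "X"
    expect_equal(chars_m[keep], chars_r[keep])
  }
})
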