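test_that("the dampening factor follows ln(|C| / (k - 0.1)) and decreases in k", {
  expect_equal(damping_factor(10, 10), log(10 / 9.9), tolerance = 1e-12)
  expect_equal(damping_factor(10, 1), log(10 / 0.9), tolerance = 1e-12)
  f <- damping_factor(10, 1:10)
  expect_true(all(diff(f) < 0))
  expect_true(all(f > 0))
  expect_error(damping_factor(10, 0), "presence_count")
  expect_error(damping_factor(10, 11), "presence_count")
  expect_error(damping_factor(1, 1), "2 classes")
})

test_that("dampening scales enriched counts by raw class presence", {
  p <- do.call(toy_profile, c(list("AAAA"),
                              setNames(as.list(c(5, rep(0, 9))), paste0("c", 1:10))))
  d <- dampen_profile(p, presence_counts(p))
  expect_equal(d$c1, 5 * log(10 / 0.9))
  expect_equal(d$c2, 0)
  everywhere <- do.call(toy_profile, c(list("CCCC"),
                                       setNames(as.list(rep(2, 10)), paste0("c", 1:10))))
  d2 <- dampen_profile(everywhere, presence_counts(everywhere))
  expect_equal(unlist(d2[paste0("c", 1:10)], use.names = FALSE),
               rep(2 * log(10 / 9.9), 10))
})

test_that("the discriminative ratio applies the three degenerate-case rules", {
  # second and third highest zero: mean forced to 1
  r <- discriminative_ratio(c(A = 7, B = 0, C = 0, D = 0))
  expect_equal(r$dr, 7)
  expect_equal(r$top_class, "A")
  # only third zero: mean equals the second highest
  r <- discriminative_ratio(c(A = 12, B = 4, C = 0))
  expect_equal(r$dr, 3)
  # fractional mean floored to 1
  r <- discriminative_ratio(c(A = 5, B = 0.6, C = 0.2))
  expect_equal(r$dr, 5)
  # ordinary case: plain ratio to the mean of 2nd and 3rd
  r <- discriminative_ratio(c(A = 50, B = 8, C = 2, D = 0))
  expect_equal(r$dr, 10)
  expect_error(discriminative_ratio(c(A = 1, B = 2)), "3 classes")
})

test_that("a top weight tied across classes is never discriminative", {
  d <- tibble::tibble(gram = "AAAA", presence = 2L, damping = 1,
                      A = 10, B = 10, C = 0)
  sel <- select_discriminative(d, 2, substitution = FALSE)
  expect_equal(nrow(sel), 0)
})

test_that("selection keeps dr >= T with a sharp boundary", {
  d <- tibble::tibble(gram = c("AAAA", "CCCC"), presence = 1L,
                      damping = 1, A = c(10, 4.99), B = 0, C = 0)
  sel <- select_discriminative(d, 5, substitution = FALSE)
  expect_equal(sel$gram, "AAAA")
  expect_equal(sel$dr, 10)
  sel10 <- select_discriminative(d, 10, substitution = FALSE)
  expect_equal(sel10$gram, "AAAA")  # dr = 10 passes T = 10 under >=
  expect_error(select_discriminative(d, 1), "exceed 1")
})

test_that("qualifying seeds emit their constituents with the combined DR", {
  data <- tibble::tibble(
    seq_id = paste0("s", 1:3), class = c("A", "B", "C"),
    residues = c("TLSNPKTLSNPKTLSDPK", "GGGGGG", "EEEEEE"))
  profile <- ngram_profile(data, 6)
  damped <- dampen_profile(enrich_profile(profile), presence_counts(profile))
  sel <- select_discriminative(damped, 2, profile = profile)
  tl <- sel[sel$seed == "TLSNPK", ]
  expect_setequal(tl$gram, c("TLSNPK", "TLSDPK"))
  expect_equal(unique(tl$display), "TLS[ND]PK")
  expect_equal(length(unique(tl$dr)), 1)
  # after dedupe every gram survives exactly once
  res <- score_ngrams(data, 6, threshold = 2)
  expect_true(all(c("TLSNPK", "TLSDPK") %in% res$gram))
  expect_equal(anyDuplicated(res$gram), 0)
})

test_that("cross-class dedupe keeps the highest DR, ties to the smaller label", {
  items <- tibble::tibble(
    gram = c("AAAA", "AAAA", "CCCC", "GGGG", "GGGG"),
    n = 4L,
    class = c("A", "B", "C", "B", "A"),
    dr = c(9, 6, 4, 5, 5),
    seed = c("AAAA", "AAAA", "CCCC", "GGGG", "GGGG"),
    display = c("AAAA", "AAAA", "CCCC", "GGGG", "GGGG"))
  out <- dedupe_ngrams(items)
  expect_equal(nrow(out), 3)
  expect_equal(out$class[out$gram == "AAAA"], "A")   # higher DR wins
  expect_equal(out$class[out$gram == "GGGG"], "A")   # tie: smaller label
  expect_equal(dedupe_ngrams(out), out)              # no duplicates: identity
})

test_that("raising the threshold never adds n-grams", {
  for (seed in c(41, 42)) {
    data <- toy_dataset(seed)
    lo <- score_ngrams(data, 4, threshold = 2)
    hi <- score_ngrams(data, 4, threshold = 4)
    expect_true(all(hi$gram %in% lo$gram))
  }
})

test_that("SF2 equals SF1 when no gram has an eligible neighbor", {
  # distinct residue pairs with non-positive BLOSUM scores across grams
  data <- tibble::tibble(
    seq_id = paste0("s", 1:3), class = c("A", "B", "C"),
    residues = c("WWWWCCCC", "PPPPGGGG", "HHHHFFFF"))
  sf1 <- score_ngrams(data, 4, threshold = 2, substitution = TRUE)
  sf2 <- score_ngrams(data, 4, threshold = 2, substitution = FALSE)
  expect_equal(sf1, sf2)
})

test_that("two-class datasets are rejected with a clear error", {
  data <- tibble::tibble(seq_id = c("s1", "s2"), class = c("A", "B"),
                         residues = c("AAAAAA", "CCCCCC"))
  expect_error(score_ngrams(data, 4, threshold = 5), "at least 3")
})
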