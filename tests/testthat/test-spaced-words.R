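test_that("default substitution matrix is symmetric with the documented signs", {
  m <- default_matrix()
  expect_true(isSymmetric(m))
  expect_true(all(diag(m) > 0))
  expect_true(all(m[upper.tri(m)] < 0))
  expect_identical(dimnames(m), list(c("A", "C", "G", "T"),
                                     c("A", "C", "G", "T")))
})

test_that("enumeration matches hand-enumerated toy cases", {
  p2 <- spaced_pattern("11")
  # ACGT both strands: revcomp(ACGT) = ACGT, 3 windows each
  idx <- enumerate_occurrences(list(t1 = "ACGT"), p2)
  expect_equal(nrow(idx$occ), 6L)
  # AAAA forward only: 3 occurrences, all in one bucket
  idx <- enumerate_occurrences(list(t1 = "AAAA"), p2, include_reverse = FALSE)
  expect_equal(nrow(idx$occ), 3L)
  expect_equal(length(idx$bucket_start), 1L)
  expect_equal(get_occurrence(idx, 1)$key, "AA")
  # record shorter than the pattern contributes nothing
  idx <- enumerate_occurrences(list(t1 = "ACG"), spaced_pattern("10101"))
  expect_equal(nrow(idx$occ), 0L)
  # empty input set
  idx <- enumerate_occurrences(setNames(list(), character()), p2)
  expect_equal(nrow(idx$occ), 0L)
})

test_that("windows with ambiguity codes are skipped with a warning", {
  expect_warning(
    idx <- enumerate_occurrences(list(t1 = "ACGNACG"), spaced_pattern("11"),
                                 include_reverse = FALSE),
    "non-ACGT")
  # windows at positions 1,2 (AC,CG) and 5,6 (AC,CG); 3 and 4 overlap N
  expect_equal(nrow(idx$occ), 4L)
})

test_that("enumeration equals the naive string-matching oracle", {
  set.seed(21)
  for (rep in 1:5) {
    seqs <- list(a = c(random_dna(80), random_dna(40)), b = random_dna(120))
    mask <- "1101001"
    idx <- enumerate_occurrences(seqs, spaced_pattern(mask))
    ref <- naive_occurrences(seqs, mask)
    expect_equal(nrow(idx$occ), nrow(ref))
    got_keys <- sort(vapply(seq_len(nrow(idx$occ)),
                            function(i) get_occurrence(idx, i)$key,
                            character(1)))
    expect_equal(got_keys, sort(ref$key))
  }
})

test_that("occurrences within a bucket preserve (taxon, strand, position)", {
  idx <- enumerate_occurrences(list(a = "AAAAA", b = "AAAA"),
                               spaced_pattern("11"))
  o <- idx$occ
  for (b in seq_along(idx$bucket_start)) {
    rng <- idx$bucket_start[b]:idx$bucket_end[b]
    key <- o$key[rng]
    expect_true(all(key == key[1]))
    ord <- order(o$taxon[rng], o$strand[rng], o$pos[rng])
    expect_equal(ord, seq_along(rng))
  }
})

test_that("score_match sums matrix entries over the whole window", {
  m <- default_matrix()
  a <- list(key = "ACTG", window = "ACGTACG")
  expect_equal(score_match(a, a, m), 91 + 100 + 100 + 91 + 91 + 100 + 100)
  b1 <- list(key = "AA", window = "ACA")
  b2 <- list(key = "AA", window = "AGA")
  expect_equal(score_match(b1, b2, m), 91 - 125 + 91)
  expect_equal(score_match(list(key = "A", window = "A"),
                           list(key = "A", window = "A"), m), 91)
  expect_error(score_match(b1, list(key = "AC", window = "ACC"), m),
               "contract violation")
})

test_that("score_match is symmetric and positive for identical windows", {
  m <- default_matrix()
  set.seed(5)
  for (i in 1:20) {
    w1 <- random_dna(15); w2 <- random_dna(15)
    a <- list(key = "K", window = w1)
    b <- list(key = "K", window = w2)
    expect_equal(score_match(a, b, m), score_match(b, a, m))
    expect_gt(score_match(a, a, m), 0)
  }
})
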