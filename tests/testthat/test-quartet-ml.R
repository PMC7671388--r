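toy_counts <- function(rows) site_pattern_counts(as_pblock(rows))

test_that("site pattern counts aggregate identical columns", {
  rows <- c(t1 = "ACGT", t2 = "ACGT", t3 = "ACGT", t4 = "ACGA")
  sc <- toy_counts(rows)
  expect_equal(sum(sc$counts), 4)
  expect_equal(ncol(sc$states), 4L)      # 3 constant + TTTA, each once
  expect_true(all(sc$counts == 1))
  # column selection by pattern
  pat <- generate_pattern(20, 6, seed = 1)
  set.seed(2)
  s <- random_dna(20)
  b <- as_pblock(setNames(rep(s, 4), paste0("t", 1:4)), pattern = pat)
  expect_equal(site_pattern_counts(b, "all")$n_sites, 20L)
  expect_equal(site_pattern_counts(b, "dontcare")$n_sites, 14L)
})

test_that("degenerate limits of the quartet likelihood", {
  pi <- c(0.1, 0.2, 0.3, 0.4)
  params <- gtr_params(base_freqs = pi, gamma_shape = Inf, n_categories = 1)
  # constant columns, all branch lengths 0: loglik = sum n_x log pi_x
  rows <- c(a = "AACCCGGGTT", b = "AACCCGGGTT", c = "AACCCGGGTT",
            d = "AACCCGGGTT")
  sc <- toy_counts(rows)
  ll0 <- quartet_loglik(sc, 1, rep(0, 5), params)
  expect_equal(ll0, 2 * log(pi[1]) + 3 * log(pi[2]) + 3 * log(pi[3]) +
                 2 * log(pi[4]), tolerance = 1e-9)
  # saturation: leaves independent, per site prod_i pi_{x_i}
  lls <- quartet_loglik(sc, 1, rep(60, 5), params)
  expect_equal(lls, 10 * sum(log(pi^4) * c(2, 3, 3, 2) / 10), tolerance = 1e-6)
})

test_that("pruning equals the 16-internal-state brute force", {
  set.seed(31)
  for (case in 1:25) {
    nsite <- 4L
    states <- matrix(sample(0:3, 4 * nsite, TRUE), 4, nsite)
    counts <- sample(1:3, nsite, TRUE)
    bl <- runif(5, 0.01, 1.5)
    exch <- runif(6, 0.3, 3); exch[6] <- 1
    pi <- runif(4, 0.5, 2); pi <- pi / sum(pi)
    alpha <- runif(1, 0.3, 3)
    params <- gtr_params(exch, pi, gamma_shape = alpha, n_categories = 4)
    sc <- list(states = states, counts = counts, n_sites = sum(counts),
               taxa = paste0("t", 1:4), freqs = pi)
    got <- quartet_loglik(sc, 1, bl, params)
    ref <- oracle_quartet_loglik(states, counts, bl, exch, pi, alpha, 4)
    expect_equal(got, ref, tolerance = 1e-10)
  }
})

test_that("likelihood is invariant under split-consistent relabeling and
           root placement", {
  set.seed(32)
  states <- matrix(sample(0:3, 4 * 6, TRUE), 4, 6)
  counts <- rep(1, 6)
  bl <- c(0.1, 0.2, 0.3, 0.4, 0.15)
  exch <- c(1.2, 2.5, 0.8, 1.1, 3.0, 1)
  pi <- c(0.3, 0.2, 0.2, 0.3)
  params <- gtr_params(exch, pi, gamma_shape = 0.7, n_categories = 4)
  sc <- function(st) list(states = st, counts = counts, n_sites = 6,
                          taxa = paste0("t", 1:4), freqs = pi)
  base <- quartet_loglik(sc(states), 1, bl, params)
  # swap the two taxa within a pair
  expect_equal(quartet_loglik(sc(states[c(2, 1, 3, 4), ]), 1,
                              bl[c(2, 1, 3, 4, 5)], params), base,
               tolerance = 1e-10)
  # swap the two pairs
  expect_equal(quartet_loglik(sc(states[c(3, 4, 1, 2), ]), 1,
                              bl[c(3, 4, 1, 2, 5)], params), base,
               tolerance = 1e-10)
  # pulley principle: rooting at the other internal node (oracle check)
  ru <- oracle_quartet_loglik(states, counts, bl, exch, pi, 0.7, 4, "u")
  rv <- oracle_quartet_loglik(states, counts, bl, exch, pi, 0.7, 4, "v")
  expect_equal(ru, rv, tolerance = 1e-10)
  expect_equal(base, ru, tolerance = 1e-10)
})

test_that("best_topology finds the obvious grouping and flags ties", {
  set.seed(33)
  # taxa 1,2 identical; 3,4 identical; pairs differ at 20 of 100 sites
  s12 <- random_dna(100)
  ch <- strsplit(s12, "")[[1]]
  flip <- sample(100, 20)
  ch[flip] <- vapply(ch[flip], function(x)
    sample(setdiff(c("A", "C", "G", "T"), x), 1), character(1))
  s34 <- paste(ch, collapse = "")
  r <- best_topology(as_pblock(c(t1 = s12, t2 = s12, t3 = s34, t4 = s34)))
  expect_false(r$inconclusive)
  expect_equal(r$best_split, 1L)
  expect_setequal(r$split_taxa[1:2], c("t1", "t2"))
  # direct loglik comparison backs the selection
  expect_gt(r$logliks["12|34"], max(r$logliks[c("13|24", "14|23")]))

  # all rows identical: label symmetry forces a tie
  r0 <- best_topology(as_pblock(setNames(rep(s12, 4), paste0("t", 1:4))))
  expect_true(r0$inconclusive)
  expect_true(is.na(r0$best_split))
  expect_lt(diff(range(r0$logliks)), 1e-6)
})

test_that("optimized loglik is at least the start-point loglik", {
  set.seed(34)
  for (i in 1:5) {
    rows <- setNames(vapply(1:4, function(k) random_dna(60), character(1)),
                     paste0("t", 1:4))
    b <- as_pblock(rows)
    sc <- site_pattern_counts(b)
    r <- suppressWarnings(best_topology(b))
    params <- gtr_params(base_freqs = sc$freqs, gamma_shape = 1,
                         n_categories = 4)
    for (s in 1:3)
      expect_gte(r$logliks[s] + 1e-9,
                 quartet_loglik(sc, s, rep(0.05, 5), params))
  }
})
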