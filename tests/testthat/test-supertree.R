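test_that("one quartet contributes exactly six edges", {
  q <- matrix(c("1", "2", "3", "4"), 1)
  g <- build_graph(q, c("1", "2", "3", "4"))
  expect_equal(g$good["1", "2"], 1)
  expect_equal(g$good["3", "4"], 1)
  expect_equal(sum(g$good), 4)            # symmetric storage
  for (p in list(c("1", "3"), c("1", "4"), c("2", "3"), c("2", "4")))
    expect_equal(g$bad[p[1], p[2]], 1)
  expect_equal(sum(g$bad), 8)
  # additivity and the empty case
  g2 <- build_graph(rbind(q, q), c("1", "2", "3", "4"))
  expect_equal(g2$good, 2 * g$good)
  expect_equal(g2$bad, 2 * g$bad)
  g0 <- build_graph(q[0, , drop = FALSE], c("1", "2", "3", "4"))
  expect_true(all(g0$good == 0) && all(g0$bad == 0))
})

test_that("partial embedding adds triplet and pair constraints", {
  q <- matrix(c("a", "b", "c", "d"), 1)
  # three taxa inside: good (a,b), bad (a,c), (b,c)
  g3 <- build_graph(q, c("a", "b", "c"), partial = TRUE)
  expect_equal(g3$good["a", "b"], 1)
  expect_equal(g3$bad["a", "c"], 1)
  expect_equal(g3$bad["b", "c"], 1)
  expect_equal(sum(g3$good), 2); expect_equal(sum(g3$bad), 4)
  # two siblings inside: one good edge; cross pair: one bad edge
  g2 <- build_graph(q, c("a", "b"), partial = TRUE)
  expect_equal(g2$good["a", "b"], 1); expect_equal(sum(g2$bad), 0)
  gx <- build_graph(q, c("a", "c"), partial = TRUE)
  expect_equal(gx$bad["a", "c"], 1); expect_equal(sum(gx$good), 0)
  # default (non-partial) ignores spanning quartets entirely
  expect_equal(sum(build_graph(q, c("a", "b", "c"))$good), 0)
})

test_that("find_cut minimizes the good/bad ratio", {
  taxa <- c("1", "2", "3", "4")
  g <- build_graph(matrix(taxa, 1), taxa)
  cut <- find_cut(g, seed = 1)
  expect_true(setequal(cut$side1, c("1", "2")) ||
                setequal(cut$side2, c("1", "2")))
  expect_equal(cut$good_cut, 0)
  expect_equal(cut$bad_cut, 4)
  # exhaustive check: (0+1)/(4+1) is the global minimum over all 7 cuts
  combos <- list("1", "2", "3", "4", c("1", "2"), c("1", "3"), c("1", "4"))
  objs <- vapply(combos, function(s) {
    m <- taxa %in% s
    (sum(g$good[m, !m]) + 1) / (sum(g$bad[m, !m]) + 1)
  }, numeric(1))
  expect_equal(cut$objective, min(objs))

  # majority rules under conflict: 9 x 12|34 vs 1 x 13|24
  q <- rbind(matrix(rep(taxa, 9), ncol = 4, byrow = TRUE),
             c("1", "3", "2", "4"))
  cut2 <- find_cut(build_graph(q, taxa), seed = 2)
  expect_true(setequal(cut2$side1, c("1", "2")) ||
                setequal(cut2$side2, c("1", "2")))

  # degenerate graphs
  g2 <- build_graph(q[0, ], c("x", "y"))
  c2 <- find_cut(g2, seed = 3)
  expect_setequal(c(c2$side1, c2$side2), c("x", "y"))
  expect_error(find_cut(build_graph(q[0, ], "x")), "contract violation")
})

test_that("single-quartet supertree is that quartet", {
  st <- build_supertree(matrix(c("a", "b", "c", "d"), 1), seed = 1)
  expect_setequal(st$tip.label, c("a", "b", "c", "d"))
  expect_equal(rf_distance(st, parse_newick("((a,b),(c,d));"))$absolute, 0)
})

test_that("conflict-free complete quartet sets are reconstructed exactly", {
  for (seed in 1:6) {
    n <- 4 + (seed %% 4) + 2          # 6..9 taxa
    tr <- random_tree(n, seed = 100 + seed)
    st <- build_supertree(quartets_of_tree(tr), seed = seed)
    expect_equal(rf_distance(st, tr)$absolute, 0,
                 label = sprintf("seed %d (n=%d)", seed, n))
  }
})

test_that("supertree tolerates a small fraction of conflicting quartets", {
  hits <- 0
  for (s in 1:8) {
    set.seed(s)
    tr <- random_tree(10, seed = s * 7)
    q <- quartets_of_tree(tr)
    corrupt <- sample(nrow(q), ceiling(0.05 * nrow(q)))
    for (i in corrupt) q[i, ] <- sample(q[i, ])
    st <- build_supertree(q, seed = s)
    if (rf_distance(st, tr)$absolute == 0) hits <- hits + 1
  }
  expect_gte(hits, 7)    # >= 90% of seeded runs in the full-size criterion
})

test_that("taxon conservation, no degree-2 nodes, orphan attachment", {
  tr <- random_tree(7, seed = 55)
  q <- quartets_of_tree(tr)
  expect_warning(st <- build_supertree(q, taxa = c(tr$tip.label, "zz"),
                                       seed = 1),
                 "attached at the root")
  expect_setequal(st$tip.label, c(tr$tip.label, "zz"))
  deg <- tabulate(st$edge, nbins = length(st$tip.label) + st$Nnode)
  expect_false(any(deg[-(1:length(st$tip.label))] == 2))
  expect_error(build_supertree(q[0, , drop = FALSE], taxa = c("a", "b")),
               "at least 4 taxa")
})

test_that("majority vote keeps one topology per subset and drops ties", {
  q <- rbind(c("a", "b", "c", "d"),
             c("c", "d", "a", "b"),      # same split, rotated
             c("a", "c", "b", "d"),
             c("a", "b", "c", "e"),
             c("a", "c", "b", "e"))      # {a,b,c,e}: 1-1 tie -> dropped
  mq <- majority_quartets(q)
  expect_equal(nrow(mq), 1L)
  expect_setequal(mq[1, 1:2], c("a", "b"))
})
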