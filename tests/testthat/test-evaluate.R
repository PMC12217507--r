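test_that("jaccard coefficient behaves as a set similarity", {
  # 50% overlap of two equal-sized sets -> 1/3
  expect_equal(jaccard(c("a", "b", "c", "d"), c("a", "b", "e", "f")), 1 / 3)
  expect_equal(jaccard(c("x", "y"), c("x", "y")), 1)
  expect_equal(jaccard("x", "y"), 0)
  expect_equal(jaccard(c("a", "a", "b"), c("b", "b", "a")), 1)  # duplicates ignored
  # symmetry and the |A∩B|/(|A|+|B|) lower bound on random sets
  set.seed(12)
  for (i in 1:20) {
    a <- sample(letters, sample(0:10, 1))
    b <- sample(letters, sample(1:10, 1))
    if (!length(a) && !length(b)) next
    expect_identical(jaccard(a, b), jaccard(b, a))
    expect_gte(jaccard(a, b), length(intersect(a, b)) / (length(a) + length(b)))
  }
  expect_warning(j0 <- jaccard(character(), character()), "empty")
  expect_equal(j0, 0)
})

test_that("consistency summarizes pairwise jaccards and the overlap spectrum", {
  h4 <- list(s1 = c("a", "b"), s2 = c("a", "b"), s3 = c("a", "b"), s4 = c("a", "b"))
  cc <- consistency(h4)
  expect_equal(cc$pairwise$jaccard, rep(1, 6))
  expect_equal(cc$median_jaccard, 1)
  expect_equal(unname(cc$overlap_counts), c(0L, 0L, 0L, 2L))

  c2 <- consistency(list(s1 = c("x", "y"), s2 = c("y", "z")))
  expect_equal(c2$median_jaccard, 1 / 3)

  # exactly-k strata partition the union
  h <- list(s1 = c("a", "b", "c"), s2 = c("b", "c"), s3 = c("c"), s4 = c("c", "d"))
  cc2 <- consistency(h)
  expect_equal(unname(cc2$overlap_counts), c(2L, 1L, 0L, 1L))
  expect_equal(sum(cc2$overlap_counts), length(unique(unlist(h))))

  # label permutation invariance
  cc3 <- consistency(h[c(3, 1, 4, 2)])
  expect_equal(cc3$median_jaccard, cc2$median_jaccard)
  expect_equal(sort(cc3$pairwise$jaccard), sort(cc2$pairwise$jaccard))

  expect_error(consistency(list(s1 = "a")), ">= 2")
})

test_that("per-comparison universes restrict hits to co-scoreable pairs", {
  hs <- list(s1 = c("a", "b", "u"), s2 = c("a", "c"))
  un <- list(s1 = c("a", "b", "c", "u"), s2 = c("a", "b", "c"))
  # "u" is not scoreable in s2, so it must not count against agreement
  cc <- consistency(hs, universes = un)
  expect_equal(cc$pairwise$jaccard, 1 / 3)  # {a,b} vs {a,c}
})

test_that("identity stratification and effect sizes", {
  h <- list(s1 = c("a", "b", "c"), s2 = c("b", "c"), s3 = c("c"))
  cc <- consistency(h)
  ids <- c(a = 80, b = 90, c = 100)
  tab <- identity_by_frequency(cc, h, ids)
  expect_equal(tab$median_identity[tab$k == 1], 80)
  expect_equal(tab$median_identity[tab$k == 3], 100)
  # missing identity -> excluded but counted
  tab2 <- identity_by_frequency(cc, h, ids[c("a", "c")])
  expect_equal(tab2$n_with_identity[tab2$k == 2], 0L)
  expect_true(is.na(tab2$median_identity[tab2$k == 2]))
  # all identities equal -> all strata medians equal
  tab3 <- identity_by_frequency(cc, h, c(a = 50, b = 50, c = 50))
  expect_true(all(tab3$median_identity == 50))

  # strata (80,90) vs (85,95): |D| = 5 / sqrt(50)
  d <- stratum_effect_size(c(80, 90), c(85, 95))
  expect_equal(abs(d), 5 / sqrt(50), tolerance = 1e-12)
  expect_equal(stratum_effect_size(c(85, 95), c(80, 90)), -d)
  expect_equal(stratum_effect_size(c(80, 90), c(80, 90)), 0)
})

test_that("expressed fraction counts cell lines where both genes exceed the cut", {
  expr <- rbind(GA = c(3, 3, 3, 3, 3, 3, 3, 3, 1, 1),
                GB = rep(5, 10),
                GC = rep(0, 10))
  colnames(expr) <- paste0("cl", 1:10)
  out <- expressed_fraction(pair_key("GA", "GB"), expr)
  expect_equal(out$fraction, 0.8)
  expect_equal(expressed_fraction(pair_key("GB", "GC"), expr)$fraction, 0)
  expect_equal(expressed_fraction(pair_key("GA", "GB"), expr, cut = 0.5)$fraction, 1)
  suppressMessages(
    miss <- expressed_fraction(c(pair_key("GA", "GZ")), expr))
  expect_true(is.na(miss$fraction))
})
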