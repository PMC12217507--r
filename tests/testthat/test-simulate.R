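test_that("simulation is deterministic given the root seed", {
  a <- small_sim(seed = 3L)
  b <- small_sim(seed = 3L)
  expect_identical(lapply(a$counts, unclass), lapply(b$counts, unclass))
  expect_identical(a$truth, b$truth)
  expect_identical(a$refs, b$refs)
  c3 <- small_sim(seed = 4L)
  expect_false(identical(unclass(a$counts[[1]]), unclass(c3$counts[[1]])))
})

test_that("config validation rejects impossible settings", {
  expect_error(sim_config(frac_sl_pairs = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(depth = -1), "depth")
  expect_error(sim_config(n_genes = 0), "positive")
  expect_error(sim_config(n_genes = 4, n_pairs = 100), "more pairs")
  expect_error(sim_config(dispersion = 0), "dispersion")
})

test_that("simulated structure matches the configuration", {
  sim <- small_sim(seed = 5L)
  cfg <- sim$config
  g <- cfg$guides_per_construct
  expect_length(sim$counts, cfg$n_screens)
  n_arrays <- (cfg$n_genes + 2L * cfg$n_controls + cfg$n_pairs) * g
  expect_identical(nrow(sim$counts[[1]]), n_arrays)
  expect_identical(nrow(sim$annotation), n_arrays)
  expect_identical(sum(sim$annotation$construct_class == "pair"), cfg$n_pairs * g)
  expect_length(sim$refs$essential, cfg$n_controls)
  n_common <- sum(sim$truth$labels == "sl_common")
  expect_length(sim$refs$sl_pairs, min(cfg$n_ref_sl, n_common))
  # reference SL pairs are drawn from the planted common SL pairs
  expect_true(all(sim$truth$labels[sim$refs$sl_pairs] == "sl_common"))
  # additive construction: context pairs carry the SL dLFC in exactly one screen
  ctx <- names(sim$truth$context_screen)
  if (length(ctx)) {
    row <- sim$truth$pair_dlfc[ctx[1], ]
    expect_identical(sum(row == cfg$dlfc_sl), 1L)
    expect_identical(names(which(row == cfg$dlfc_sl)),
                     unname(sim$truth$context_screen[ctx[1]]))
  }
})

test_that("noise-free Poisson counts at high depth recover the planted LFCs", {
  sim <- simulate_screens(sim_config(
    n_genes = 120L, n_pairs = 60L, n_screens = 1L, guide_noise_sd = 0,
    dispersion = Inf, depth = 5e7, seed = 21L))
  norm <- normalize_counts(sim$counts[[1]], pseudocount = 0)
  agg <- aggregate_gene_lfc(guide_lfc(norm), sim$annotation)
  truth <- sim$truth$gene_lfc[, 1]
  # depth renormalization shifts all LFCs by a common constant; compare centered
  est <- agg$single[names(truth)]
  shift <- median(est - truth)
  expect_lt(max(abs(est - truth - shift)), 0.1)
})

test_that("with no planted interactions, hit counts stay at the null rate", {
  sim <- simulate_screens(sim_config(n_genes = 600L, n_pairs = 500L,
                                     n_screens = 1L, frac_sl_pairs = 0,
                                     seed = 31L))
  fit <- paralog_gi(sim$counts, sim$annotation, refs = NULL, seed = 31L)
  n_hits <- lengths(hits(fit, "zdlfc"))
  expect_lte(max(n_hits), 0.02 * length(fit$pairs))
})

test_that("recall at fixed thresholds increases with interaction strength", {
  recall_at <- function(effect) {
    sim <- simulate_screens(sim_config(n_genes = 300L, n_pairs = 150L,
                                       n_screens = 1L, dlfc_sl = effect,
                                       guide_noise_sd = 0.6, dispersion = 10,
                                       seed = 17L))
    fit <- paralog_gi(sim$counts, sim$annotation, seed = 17L)
    truth_metrics(hits(fit, "zdlfc"), sim$truth)$recall_common
  }
  r <- vapply(c(-0.8, -1.6, -3), recall_at, numeric(1))
  expect_true(all(diff(r) >= 0))
  expect_gt(r[3], r[1])
})

test_that("truth metrics score hit sets against the planted labels", {
  truth <- list(labels = c("a|b" = "sl_common", "c|d" = "sl_common",
                           "e|f" = "sl_context", "g|h" = "null", "i|j" = "null"),
                context_screen = c("e|f" = "s2"))
  # hits exactly = positives in s2 -> precision = recall = 1
  m <- truth_metrics(list(s2 = c("a|b", "c|d", "e|f")), truth)
  expect_equal(c(m$precision, m$recall, m$fpr), c(1, 1, 0))
  # context pair is not a positive outside its active screen
  m1 <- truth_metrics(list(s1 = c("e|f")), truth)
  expect_equal(m1$fp, 1L)
  expect_equal(m1$recall, 0)
  # empty hit set -> recall 0, precision undefined
  m0 <- truth_metrics(list(s1 = character()), truth)
  expect_true(is.na(m0$precision))
  expect_equal(m0$recall, 0)
  # half of planted found, no false positives
  mh <- truth_metrics(list(s1 = "a|b"), truth)
  expect_equal(mh$precision, 1)
  expect_equal(mh$recall, 0.5)
})
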