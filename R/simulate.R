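#' Configuration for the synthetic screen generator
#'
#' Defaults describe a mid-sized multiplex paralog screen: 1000 genes with
#' single-knockout constructs, 500 paralog pairs, 4 constructs ("guides")
#' per target, 4 cell lines, 10% essential singles (knockout LFC -2), 10%
#' synthetic-lethal pairs (dLFC -2) of which 20% are context-specific
#' (active in a single randomly chosen screen), 50 + 50
#' essential/nonessential control singles, per-guide effect noise sd 0.3
#' (log2 units), negative-binomial counts with size 50 and 1e7 reads per
#' sample.
#'
#' @param n_genes Number of library genes with single-knockout arrays.
#' @param n_pairs Number of paralog pairs (sampled among the genes).
#' @param guides_per_construct Arrays per target (single gene or pair).
#' @param n_screens Number of simulated cell lines.
#' @param frac_essential_singles Fraction of library genes that are
#'   essential (true LFC = `lfc_essential`).
#' @param frac_sl_pairs Fraction of pairs that are synthetic lethal.
#' @param frac_context_specific Fraction of SL pairs active in only one
#'   (random) screen.
#' @param n_controls Essential and nonessential control singles added to
#'   the library (each).
#' @param n_ref_sl Number of common SL pairs emitted as the
#'   positive-control reference set (for RdLFC).
#' @param lfc_essential True single-knockout LFC of essential genes
#'   (log2 units).
#' @param dlfc_sl True interaction dLFC of synthetic-lethal pairs.
#' @param guide_noise_sd Per-guide effect noise sd (log2 units).
#' @param dispersion Negative-binomial size parameter of the count draws
#'   (larger = closer to Poisson; `Inf` gives exact Poisson counts).
#' @param depth Expected total reads per sample.
#' @param seed Root seed; all randomness derives from it.
#' @return Validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_genes = 1000L, n_pairs = 500L,
                       guides_per_construct = 4L, n_screens = 4L,
                       frac_essential_singles = 0.1, frac_sl_pairs = 0.1,
                       frac_context_specific = 0.2,
                       n_controls = 50L, n_ref_sl = 13L,
                       lfc_essential = -2, dlfc_sl = -2,
                       guide_noise_sd = 0.3, dispersion = 50,
                       depth = 1e7, seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), n_pairs = as.integer(n_pairs),
              guides_per_construct = as.integer(guides_per_construct),
              n_screens = as.integer(n_screens),
              frac_essential_singles = frac_essential_singles,
              frac_sl_pairs = frac_sl_pairs,
              frac_context_specific = frac_context_specific,
              n_controls = as.integer(n_controls),
              n_ref_sl = as.integer(n_ref_sl),
              lfc_essential = lfc_essential, dlfc_sl = dlfc_sl,
              guide_noise_sd = guide_noise_sd, dispersion = dispersion,
              depth = depth, seed = as.integer(seed))
  probs <- c(cfg$frac_essential_singles, cfg$frac_sl_pairs,
             cfg$frac_context_specific)
  if (any(probs < 0 | probs > 1)) stop("fractions must be in [0, 1]")
  if (cfg$depth <= 0) stop("depth must be positive")
  if (any(c(cfg$n_genes, cfg$n_pairs, cfg$guides_per_construct,
            cfg$n_screens) < 1L)) stop("counts must be positive")
  if (cfg$guide_noise_sd < 0) stop("guide_noise_sd must be >= 0")
  if (cfg$dispersion <= 0) stop("dispersion must be positive")
  if (cfg$n_pairs > choose(cfg$n_genes, 2))
    stop("more pairs requested than distinct gene pairs available")
  structure(cfg, class = "sim_config")
}

# derived substream seed, kept below 2^31 so set.seed() accepts it
sub_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) + 104729 * stream) %% 2147483647)
}

# negative-binomial draw with Poisson limit at infinite size
rcounts <- function(n, mu, size) {
  if (is.infinite(size)) stats::rpois(n, mu) else stats::rnbinom(n, mu = mu, size = size)
}

#' Simulate multi-screen paralog knockout count data with known truth
#'
#' Builds a library of single-gene and pair constructs (plus
#' essential/nonessential control singles), plants true fitness effects —
#' essential genes drop out at `lfc_essential`, synthetic-lethal pairs get
#' an extra interaction dLFC of `dlfc_sl` on top of the additive
#' single-gene expectation — and draws sequencing counts per screen:
#' T0 counts negative-binomially around a uniform per-array depth,
#' endpoint mean counts scaled by `2^effect` with per-guide Gaussian
#' effect noise, endpoint counts drawn negative-binomially, and every
#' sample rescaled to the target depth.
#'
#' Each screen uses its own substream seed derived from the root seed, so
#' screens are independently reproducible and the whole output is
#' deterministic given `cfg$seed`.
#'
#' @param cfg A `"sim_config"` object.
#' @return List with `counts` (named list of `"gi_counts"`, one per
#'   screen), `annotation` (`"gi_annotation"`), `refs` (`"gi_refs"` with
#'   controls and the reference SL subset), and `truth` (list: `gene_lfc`
#'   gene x screen matrix, `pair_dlfc` pair x screen matrix, `labels`
#'   named vector in {sl_common, sl_context, null}, `context_screen`
#'   named vector for context-specific pairs).
#' @export
simulate_screens <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  g <- cfg$guides_per_construct
  screens <- sprintf("screen%d", seq_len(cfg$n_screens))

  genes <- sprintf("G%04d", seq_len(cfg$n_genes))
  ess_ctrl <- sprintf("ESSC%02d", seq_len(cfg$n_controls))
  non_ctrl <- sprintf("NESC%02d", seq_len(cfg$n_controls))

  n_ess <- round(cfg$frac_essential_singles * cfg$n_genes)
  essential_genes <- sample(genes, n_ess)
  gene_lfc_true <- stats::setNames(rep(0, cfg$n_genes), genes)
  gene_lfc_true[essential_genes] <- cfg$lfc_essential
  ctrl_lfc <- stats::setNames(c(rep(cfg$lfc_essential, cfg$n_controls),
                                rep(0, cfg$n_controls)),
                              c(ess_ctrl, non_ctrl))

  # distinct unordered pairs, rejection-sampled on canonical keys
  pair_keys <- character(0)
  while (length(pair_keys) < cfg$n_pairs) {
    a <- sample(genes, cfg$n_pairs, replace = TRUE)
    b <- sample(genes, cfg$n_pairs, replace = TRUE)
    ok <- a != b
    pair_keys <- unique(c(pair_keys, pair_key(a[ok], b[ok])))
  }
  pair_keys <- pair_keys[seq_len(cfg$n_pairs)]

  n_sl <- round(cfg$frac_sl_pairs * cfg$n_pairs)
  sl_pairs <- sample(pair_keys, n_sl)
  n_ctx <- round(cfg$frac_context_specific * n_sl)
  ctx_pairs <- if (n_ctx > 0) sample(sl_pairs, n_ctx) else character(0)
  common_sl <- setdiff(sl_pairs, ctx_pairs)
  labels <- stats::setNames(rep("null", cfg$n_pairs), pair_keys)
  labels[common_sl] <- "sl_common"
  labels[ctx_pairs] <- "sl_context"
  context_screen <- stats::setNames(
    sample(screens, length(ctx_pairs), replace = TRUE), ctx_pairs)

  all_single <- c(genes, ess_ctrl, non_ctrl)
  single_lfc_all <- c(gene_lfc_true, ctrl_lfc)
  gene_lfc <- matrix(single_lfc_all, nrow = length(all_single),
                     ncol = cfg$n_screens,
                     dimnames = list(all_single, screens))
  pair_dlfc <- matrix(0, nrow = cfg$n_pairs, ncol = cfg$n_screens,
                      dimnames = list(pair_keys, screens))
  pair_dlfc[common_sl, ] <- cfg$dlfc_sl
  for (p in ctx_pairs) pair_dlfc[p, context_screen[[p]]] <- cfg$dlfc_sl

  # annotation: g arrays per single and per pair
  pg <- pair_genes(pair_keys)
  ann_df <- data.frame(
    array_id = c(sprintf("%s_arr%d", rep(all_single, each = g), seq_len(g)),
                 sprintf("%s_arr%d", rep(gsub("|", "_", pair_keys, fixed = TRUE),
                                         each = g), seq_len(g))),
    gene1 = c(rep(all_single, each = g), rep(pg[, "gene_a"], each = g)),
    gene2 = c(rep(NA_character_, length(all_single) * g),
              rep(pg[, "gene_b"], each = g)),
    control_class = c(rep("none", cfg$n_genes * g),
                      rep("essential_ctrl", cfg$n_controls * g),
                      rep("nonessential_ctrl", cfg$n_controls * g),
                      rep("none", cfg$n_pairs * g)),
    stringsAsFactors = FALSE)
  ann <- gi_annotation(ann_df)

  # true per-array effect (before guide noise): total LFC of the target
  pair_total <- function(j) gene_lfc[pg[, "gene_a"], j] +
    gene_lfc[pg[, "gene_b"], j] + pair_dlfc[, j]
  n_arrays <- nrow(ann)
  mu0 <- cfg$depth / n_arrays

  counts <- vector("list", cfg$n_screens); names(counts) <- screens
  for (s in seq_len(cfg$n_screens)) {
    j <- screens[s]
    set.seed(sub_seed(cfg$seed, s))
    effect <- c(rep(gene_lfc[, j], each = g), rep(pair_total(j), each = g)) +
      stats::rnorm(n_arrays, 0, cfg$guide_noise_sd)
    t0 <- rcounts(n_arrays, mu0, cfg$dispersion)
    ep <- rcounts(n_arrays, mu0 * 2^effect, cfg$dispersion)
    m <- cbind(T0 = round(t0 * cfg$depth / max(sum(t0), 1)),
               endpoint = round(ep * cfg$depth / max(sum(ep), 1)))
    rownames(m) <- ann$array_id
    counts[[j]] <- gi_counts(m, t0 = "T0")
  }

  ref_sl <- sample(common_sl, min(cfg$n_ref_sl, length(common_sl)))
  refs <- reference_sets(essential = ess_ctrl, nonessential = non_ctrl,
                         sl_pairs = ref_sl)

  list(counts = counts, annotation = ann, refs = refs,
       truth = list(gene_lfc = gene_lfc, pair_dlfc = pair_dlfc,
                    labels = labels, context_screen = context_screen),
       config = cfg)
}

#' Precision, recall and false-positive rate against planted truth
#'
#' For each screen, positives are the common synthetic-lethal pairs plus
#' any context-specific pair active in that screen; all other pairs in
#' the truth universe are negatives. Precision is NA (with a flag) for an
#' empty hit set.
#'
#' @param hit_sets Named list: screen -> vector of hit pair keys.
#' @param truth The `truth` element of [simulate_screens()] output.
#' @return data.frame per screen: `screen`, `n_hits`, `tp`, `fp`,
#'   `precision`, `recall`, `fpr`, plus the same metrics restricted to
#'   common SL pairs (`recall_common`).
#' @export
truth_metrics <- function(hit_sets, truth) {
  universe <- names(truth$labels)
  common <- universe[truth$labels == "sl_common"]
  out <- lapply(names(hit_sets), function(j) {
    pos <- c(common, names(truth$context_screen)[truth$context_screen == j])
    neg <- setdiff(universe, pos)
    h <- intersect(hit_sets[[j]], universe)
    tp <- length(intersect(h, pos)); fp <- length(intersect(h, neg))
    data.frame(screen = j, n_hits = length(h), tp = tp, fp = fp,
               precision = if (length(h)) tp / length(h) else NA_real_,
               recall = if (length(pos)) tp / length(pos) else NA_real_,
               fpr = if (length(neg)) fp / length(neg) else NA_real_,
               recall_common = if (length(common))
                 length(intersect(h, common)) / length(common) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
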