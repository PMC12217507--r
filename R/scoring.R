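#' Hit-calling thresholds
#'
#' All cuts are strict upper bounds: a pair is a hit when its score is
#' strictly below the cut. Defaults follow the standard choices for the
#' three scoring methods: raw dLFC hits require a strong interaction
#' (dLFC < -1) in a pair whose knockout itself drops out (pair LFC < -1);
#' ZdLFC hits require ZdLFC < -2 and pair ZLFC < -2; RdLFC hits require
#' RdLFC < -0.7 and pair ZLFC < -2 (the -0.7 chosen to yield roughly as
#' many hits as the ZdLFC rule, so methods are compared at matched set
#' sizes).
#'
#' @param dlfc_cut,lfc_cut,zdlfc_cut,zlfc_cut,rdlfc_cut Numeric cuts.
#' @return List of class `"gi_thresholds"`.
#' @export
gi_thresholds <- function(dlfc_cut = -1, lfc_cut = -1,
                          zdlfc_cut = -2, zlfc_cut = -2, rdlfc_cut = -0.7) {
  structure(list(dlfc_cut = dlfc_cut, lfc_cut = lfc_cut,
                 zdlfc_cut = zdlfc_cut, zlfc_cut = zlfc_cut,
                 rdlfc_cut = rdlfc_cut),
            class = "gi_thresholds")
}

#' Delta log fold change against the additive expectation
#'
#' For each pair (A, B): `expected = LFC_A + LFC_B` (sum of the member
#' single-knockout LFCs) and `dlfc = observed - expected`, where observed
#' is the pair-construct LFC. A negative dLFC means the double knockout is
#' less fit than the single-knockout effects predict — the signature of
#' synthetic lethality.
#'
#' Pairs missing the pair LFC or either single LFC are returned with NA
#' scores and a reason, never silently dropped.
#'
#' @param agg Aggregated LFCs from [aggregate_gene_lfc()].
#' @param pairs Character vector of canonical pair keys to score; defaults
#'   to every pair with a pair-level LFC.
#' @return data.frame: `pair`, `gene_a`, `gene_b`, `observed_lfc`,
#'   `expected_lfc`, `dlfc`, `reason` (NA when scored).
#' @export
compute_dlfc <- function(agg, pairs = names(agg$pair)) {
  if (!length(pairs)) {
    return(data.frame(pair = character(), gene_a = character(),
                      gene_b = character(), observed_lfc = numeric(),
                      expected_lfc = numeric(), dlfc = numeric(),
                      reason = character(), stringsAsFactors = FALSE))
  }
  g <- pair_genes(pairs)
  observed <- unname(agg$pair[pairs])
  lfc_a <- unname(agg$single[g[, "gene_a"]])
  lfc_b <- unname(agg$single[g[, "gene_b"]])
  expected <- lfc_a + lfc_b
  reason <- rep(NA_character_, length(pairs))
  reason[is.na(observed)] <- "no pair-construct LFC"
  reason[is.na(reason) & (is.na(lfc_a) | is.na(lfc_b))] <- "missing single-gene LFC"
  data.frame(pair = pairs, gene_a = g[, "gene_a"], gene_b = g[, "gene_b"],
             observed_lfc = observed, expected_lfc = expected,
             dlfc = observed - expected, reason = reason,
             stringsAsFactors = FALSE)
}

#' Z-transformed dLFC
#'
#' Standardizes dLFC against the screen's trimmed Gaussian null:
#' `zdlfc = (dlfc - mu) / sigma`.
#'
#' @param dlfc Numeric vector.
#' @param null A `"gi_null"` from [fit_dlfc_null()].
#' @return Numeric vector of ZdLFC values.
#' @export
z_dlfc <- function(dlfc, null) {
  stopifnot(inherits(null, "gi_null"))
  (dlfc - null$mu) / null$sigma
}

#' Rescaled dLFC anchored to a positive-control reference set
#'
#' Affine rescaling of dLFC that maps the null-model mean to 0 and the
#' median dLFC of the reference synthetic-lethal pairs (observed in the
#' same screen) to -1:
#' `rdlfc = (dlfc - mu) / (mu - median(dlfc[reference pairs]))`.
#'
#' @param dlfc Named numeric vector (names = canonical pair keys).
#' @param null A `"gi_null"` for the same screen.
#' @param ref_pairs Character vector of reference pair keys.
#' @return Numeric vector of RdLFC values (same order as `dlfc`).
#' @export
r_dlfc <- function(dlfc, null, ref_pairs) {
  stopifnot(inherits(null, "gi_null"))
  if (is.null(names(dlfc))) stop("dlfc must be named by pair key")
  ref <- dlfc[names(dlfc) %in% ref_pairs]
  ref <- ref[is.finite(ref)]
  if (!length(ref)) {
    warning("no reference synthetic-lethal pair scored in this screen; RdLFC omitted")
    return(rep(NA_real_, length(dlfc)))
  }
  denom <- null$mu - stats::median(ref)
  if (denom <= 0)
    stop("reference-set median dLFC (", signif(stats::median(ref), 4),
         ") is not below the null mean (", signif(null$mu, 4),
         "); rescaling is meaningless")
  (dlfc - null$mu) / denom
}

#' Call synthetic-lethal hits from a score table
#'
#' Hit definitions (all inequalities strict):
#' \describe{
#'   \item{dlfc}{`dlfc < dlfc_cut` and pair `observed_lfc < lfc_cut`}
#'   \item{zdlfc}{`zdlfc < zdlfc_cut` and pair `zlfc < zlfc_cut`}
#'   \item{rdlfc}{`rdlfc < rdlfc_cut` and pair `zlfc < zlfc_cut`}
#' }
#' Pairs with any required score missing are never hits.
#'
#' @param scores data.frame with columns `dlfc`, `observed_lfc`, `zdlfc`,
#'   `zlfc`, `rdlfc` as available (see [paralog_gi()]).
#' @param thresholds A `"gi_thresholds"` object.
#' @param method One of `"dlfc"`, `"zdlfc"`, `"rdlfc"`.
#' @return Logical vector, one element per row of `scores`.
#' @export
call_hits <- function(scores, thresholds = gi_thresholds(),
                      method = c("dlfc", "zdlfc", "rdlfc")) {
  method <- match.arg(method)
  th <- thresholds
  hit <- switch(method,
    dlfc  = scores$dlfc < th$dlfc_cut & scores$observed_lfc < th$lfc_cut,
    zdlfc = scores$zdlfc < th$zdlfc_cut & scores$zlfc < th$zlfc_cut,
    rdlfc = scores$rdlfc < th$rdlfc_cut & scores$zlfc < th$zlfc_cut)
  hit & !is.na(hit)
}
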