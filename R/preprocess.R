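#' Depth-normalize screen read counts
#'
#' Adds a pseudocount to every array in every sample, then scales each
#' sample column to a fixed total read count. This is the standard
#' preprocessing for pooled-library screens: the pseudocount stabilizes
#' log ratios for low-count arrays and the fixed depth removes sequencing
#' depth differences between samples.
#'
#' @param cm A `"gi_counts"` matrix (see [gi_counts()]), or any numeric
#'   matrix with array rownames and sample colnames.
#' @param pseudocount Reads added to every array in every sample before
#'   normalization (default 5).
#' @param depth Target total read count per sample (default 1e7).
#' @return Numeric matrix of the same shape; each column sums to `depth`.
#'   The `t0` attribute of the input is carried over.
#' @export
normalize_counts <- function(cm, pseudocount = 5, depth = 1e7) {
  m <- unclass(cm) + pseudocount
  tot <- colSums(m)
  if (any(tot <= 0))
    stop("sample '", colnames(m)[which(tot <= 0)[1L]],
         "' has zero total reads after pseudocount; cannot normalize")
  out <- sweep(m, 2L, tot, "/") * depth
  attr(out, "t0") <- attr(cm, "t0")
  out
}

#' Guide-level log2 fold change
#'
#' LFC for array i is `log2(endpoint_i / t0_i)` on depth-normalized counts.
#' When a screen has several endpoint samples (replicates or time points),
#' the per-endpoint LFCs are averaged per array, preserving each
#' replicate's own depth normalization.
#'
#' @param norm Normalized matrix from [normalize_counts()] (must carry a
#'   `t0` attribute, or pass `t0` explicitly).
#' @param t0 Name of the T0 column; defaults to the matrix's `t0` attribute.
#' @return Named numeric vector: one LFC (log2 units) per array.
#' @export
guide_lfc <- function(norm, t0 = attr(norm, "t0")) {
  if (is.null(t0)) stop("no T0 sample designated")
  if (!t0 %in% colnames(norm)) stop("T0 sample '", t0, "' not found")
  ref <- norm[, t0]
  if (any(ref <= 0))
    stop("zero normalized T0 count for array '",
         rownames(norm)[which(ref <= 0)[1L]],
         "'; use a positive pseudocount")
  ends <- setdiff(colnames(norm), t0)
  lfc <- log2(norm[, ends, drop = FALSE] / ref)
  rowMeans(lfc)
}

#' Aggregate guide-level LFC to target level
#'
#' Averages the guide-level LFCs of all arrays sharing an identical target
#' set. Single-gene arrays and pair arrays are aggregated separately: a
#' single-gene LFC for gene A never includes pair arrays that contain A.
#'
#' @param lfc Named numeric vector from [guide_lfc()] (names = array ids).
#' @param ann `"gi_annotation"` covering every array in `lfc`.
#' @return List with `single` (named vector, gene -> LFC) and `pair`
#'   (named vector, canonical pair key -> LFC).
#' @export
aggregate_gene_lfc <- function(lfc, ann) {
  idx <- match(names(lfc), ann$array_id)
  if (anyNA(idx))
    stop("array '", names(lfc)[which(is.na(idx))[1L]], "' is not annotated")
  cls <- ann$construct_class[idx]
  key <- ann$target_key[idx]
  agg <- function(sel) {
    if (!any(sel)) return(stats::setNames(numeric(0), character(0)))
    v <- tapply(lfc[sel], key[sel], mean)
    stats::setNames(as.numeric(v), names(v))
  }
  list(single = agg(cls == "single"), pair = agg(cls == "pair"))
}

#' Pooled-standard-deviation Cohen's D
#'
#' Effect size between two groups: difference of means divided by the
#' pooled standard deviation (sample-variance, n-1 convention). Used both
#' as a screen quality score (nonessential vs essential controls) and as a
#' stratum effect size in the evaluation module.
#'
#' @param x,y Numeric vectors (each of length >= 2).
#' @return `(mean(x) - mean(y)) / pooled_sd`, or `NA` with a warning when
#'   the pooled sd is zero.
#' @export
cohens_d <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2L || n2 < 2L) stop("Cohen's D needs >= 2 values per group")
  sp <- sqrt(((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2))
  if (sp == 0) {
    warning("pooled standard deviation is zero; Cohen's D undefined")
    return(NA_real_)
  }
  (mean(x) - mean(y)) / sp
}

#' Screen quality control from essential/nonessential control singles
#'
#' Computes the screen quality score: Cohen's D separating the LFC of
#' nonessential-control from essential-control single-gene knockouts
#' (larger = cleaner dropout of essentials = better screen).
#'
#' @param lfc Guide-level LFC vector from [guide_lfc()].
#' @param ann `"gi_annotation"`.
#' @param level `"gene"` (default) aggregates control guides per gene
#'   first; `"guide"` uses raw guide-level LFCs.
#' @return List of class `"gi_qc"`: `cohens_d`, `n_essential`,
#'   `n_nonessential`, `level`.
#' @export
qc_cohens_d <- function(lfc, ann, level = c("gene", "guide")) {
  level <- match.arg(level)
  idx <- match(names(lfc), ann$array_id)
  single <- ann$construct_class[idx] == "single"
  ctrl <- ann$control_class[idx]
  pick <- function(which_ctrl) {
    sel <- single & ctrl == which_ctrl
    if (level == "gene" && any(sel)) {
      as.numeric(tapply(lfc[sel], ann$target_key[idx][sel], mean))
    } else lfc[sel]
  }
  ess <- pick("essential_ctrl")
  non <- pick("nonessential_ctrl")
  if (length(ess) < 2L || length(non) < 2L)
    stop("need >= 2 essential-control and >= 2 nonessential-control singles for QC")
  d <- withCallingHandlers(
    cohens_d(non, ess),
    warning = function(w) invokeRestart("muffleWarning"))
  structure(list(cohens_d = d, n_essential = length(ess),
                 n_nonessential = length(non), level = level),
            class = "gi_qc")
}

#' @export
print.gi_qc <- function(x, ...) {
  cat(sprintf("Screen QC (Cohen's D, %s-level controls): %s\n", x$level,
              if (is.na(x$cohens_d)) "undefined (zero pooled sd)"
              else sprintf("%.3f", x$cohens_d)))
  cat(sprintf("  essential controls: %d   nonessential controls: %d\n",
              x$n_essential, x$n_nonessential))
  invisible(x)
}
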