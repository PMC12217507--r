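#' Score genetic interactions in multiplex paralog knockout screens
#'
#' The main fitting function. Takes raw read counts for one or more
#' screens, preprocesses them (pseudocount, depth normalization, guide
#' log2 fold change, gene/pair aggregation), fits the two Gaussian null
#' models per screen — a two-component mixture over all guide-level LFCs
#' (ZLFC null) and a Tukey-trimmed single Gaussian over pair dLFCs (ZdLFC
#' null) — and computes dLFC, ZdLFC and (when a reference set is supplied)
#' RdLFC scores with hit calls for every scoreable pair in every screen.
#'
#' @param counts A `"gi_counts"` object or a named list of them, one per
#'   screen (list names become screen names).
#' @param annotation A `"gi_annotation"` covering every array.
#' @param refs Optional `"gi_refs"` from [reference_sets()]. The
#'   essential / nonessential gene sets drive QC; `sl_pairs` enables
#'   RdLFC.
#' @param thresholds `"gi_thresholds"` used for hit flags.
#' @param pseudocount,depth Passed to [normalize_counts()].
#' @param common_pairs If TRUE (default) restrict scoring to pairs
#'   scoreable in every screen, so cross-screen comparisons share one
#'   universe; if FALSE each screen scores all its own pairs.
#' @param seed Integer seed for the mixture-fit restarts.
#' @return Object of class `"paralog_gi"`: list with elements
#'   `scores` (long data.frame, one row per pair per screen, columns as in
#'   [write_scores()] plus `pair`), `mixtures`, `nulls` (per-screen model
#'   fits), `qc` (per-screen [qc_cohens_d()] results, when controls are
#'   present), `thresholds`, `screens`, `pairs`, `refs`, `call`.
#' @seealso [hits()], [consistency()], [simulate_screens()]
#' @export
paralog_gi <- function(counts, annotation, refs = NULL,
                       thresholds = gi_thresholds(),
                       pseudocount = 5, depth = 1e7,
                       common_pairs = TRUE, seed = 1L) {
  if (inherits(counts, "gi_counts")) counts <- list(screen1 = counts)
  if (is.null(names(counts)) || any(!nzchar(names(counts))))
    stop("'counts' must be a named list (one element per screen)")
  if (!inherits(annotation, "gi_annotation"))
    annotation <- gi_annotation(annotation)
  if (!is.null(refs) && !inherits(refs, "gi_refs"))
    stop("'refs' must come from reference_sets()")
  screens <- names(counts)

  # annotation-driven control classes override/augment refs for QC
  ann <- annotation
  if (!is.null(refs) && length(refs$essential)) {
    sngl <- ann$construct_class == "single"
    ann$control_class[sngl & ann$gene1 %in% refs$essential] <- "essential_ctrl"
    ann$control_class[sngl & ann$gene1 %in% refs$nonessential] <- "nonessential_ctrl"
  }

  agg <- vector("list", length(screens)); names(agg) <- screens
  glfc <- vector("list", length(screens)); names(glfc) <- screens
  qc <- list(); mixtures <- list()
  for (j in screens) {
    norm <- normalize_counts(counts[[j]], pseudocount = pseudocount, depth = depth)
    glfc[[j]] <- guide_lfc(norm)
    agg[[j]] <- aggregate_gene_lfc(glfc[[j]], ann)
    qc[[j]] <- tryCatch(qc_cohens_d(glfc[[j]], ann), error = function(e) NULL)
    mixtures[[j]] <- fit_lfc_mixture(glfc[[j]], seed = seed)
  }

  pair_sets <- lapply(screens, function(j) {
    d <- compute_dlfc(agg[[j]])
    d$pair[is.na(d$reason)]
  })
  universe <- if (common_pairs) Reduce(intersect, pair_sets)
              else Reduce(union, pair_sets)
  if (!length(universe)) stop("no scoreable paralog pair in the supplied screens")

  nulls <- list(); rows <- list()
  for (j in screens) {
    d <- compute_dlfc(agg[[j]], pairs = universe)
    dl <- stats::setNames(d$dlfc, d$pair)
    nulls[[j]] <- fit_dlfc_null(dl[is.finite(dl)])
    d$zlfc <- z_lfc(d$observed_lfc, mixtures[[j]])
    d$zdlfc <- z_dlfc(d$dlfc, nulls[[j]])
    d$rdlfc <- if (!is.null(refs) && length(refs$sl_pairs))
      r_dlfc(dl, nulls[[j]], refs$sl_pairs) else NA_real_
    d$screen <- j
    d$hit_dlfc <- call_hits(d, thresholds, "dlfc")
    d$hit_zdlfc <- call_hits(d, thresholds, "zdlfc")
    d$hit_rdlfc <- if (!is.null(refs) && length(refs$sl_pairs))
      call_hits(d, thresholds, "rdlfc") else NA
    rows[[j]] <- d
  }
  scores <- do.call(rbind, rows)
  rownames(scores) <- NULL
  scores <- scores[c("pair", score_columns(), "reason")]

  structure(list(scores = scores, mixtures = mixtures, nulls = nulls,
                 qc = qc, thresholds = thresholds, screens = screens,
                 pairs = universe, refs = refs,
                 guide_lfc = glfc, gene_lfc = agg,
                 call = match.call()),
            class = "paralog_gi")
}

#' Extract per-screen hit sets from a fitted screen analysis
#'
#' @param object A `"paralog_gi"` object.
#' @param method Scoring method whose hit flags to extract.
#' @param ... Unused.
#' @return Named list: screen -> character vector of canonical pair keys.
#' @export
hits <- function(object, ...) UseMethod("hits")

#' @rdname hits
#' @export
hits.paralog_gi <- function(object, method = c("zdlfc", "dlfc", "rdlfc"), ...) {
  method <- match.arg(method)
  col <- paste0("hit_", method)
  sc <- object$scores
  out <- lapply(object$screens, function(j)
    sc$pair[sc$screen == j & !is.na(sc[[col]]) & sc[[col]]])
  names(out) <- object$screens
  out
}

#' @export
print.paralog_gi <- function(x, ...) {
  cat("Paralog genetic-interaction screen analysis\n")
  cat(sprintf("  %d screen(s): %s\n", length(x$screens),
              paste(x$screens, collapse = ", ")))
  cat(sprintf("  %d paralog pairs scored%s\n", length(x$pairs),
              if (length(x$screens) > 1L) " (common universe)" else ""))
  for (m in c("dlfc", "zdlfc", "rdlfc")) {
    h <- hits(x, m)
    if (m == "rdlfc" && (is.null(x$refs) || !length(x$refs$sl_pairs))) {
      cat("  rdlfc : not scored (no reference SL set supplied)\n")
    } else {
      cat(sprintf("  %-5s hits per screen: %s\n", m,
                  paste(sprintf("%s=%d", names(h), lengths(h)), collapse = "  ")))
    }
  }
  invisible(x)
}

#' @export
summary.paralog_gi <- function(object, ...) {
  x <- object
  cat("Paralog genetic-interaction screen analysis\n\n")
  cat("Screen QC (Cohen's D, nonessential vs essential controls):\n")
  for (j in x$screens) {
    if (is.null(x$qc[[j]])) cat(sprintf("  %s: no control singles\n", j))
    else cat(sprintf("  %s: D = %.2f (%d ess / %d noness controls)\n", j,
                     x$qc[[j]]$cohens_d, x$qc[[j]]$n_essential,
                     x$qc[[j]]$n_nonessential))
  }
  cat("\nLFC mixture null (higher-weight component) per screen:\n")
  for (j in x$screens) {
    mm <- x$mixtures[[j]]; k <- mm$null_component
    cat(sprintf("  %s: weight %.3f  mean %7.4f  sd %.4f\n",
                j, mm$weights[k], mm$means[k], mm$sds[k]))
  }
  cat("\ndLFC null model (Tukey-trimmed Gaussian) per screen:\n")
  for (j in x$screens) {
    nm <- x$nulls[[j]]
    cat(sprintf("  %s: mu %8.4f  sigma %.4f  (retained %d/%d pairs)\n",
                j, nm$mu, nm$sigma, nm$n_used, nm$n_total))
  }
  cat("\n")
  print(x)
  invisible(x)
}

#' @export
coef.paralog_gi <- function(object, ...) {
  t(vapply(object$screens, function(j) {
    mm <- object$mixtures[[j]]; k <- mm$null_component
    nm <- object$nulls[[j]]
    c(lfc_null_mean = mm$means[k], lfc_null_sd = mm$sds[k],
      lfc_null_weight = mm$weights[k],
      dlfc_null_mu = nm$mu, dlfc_null_sigma = nm$sigma)
  }, numeric(5)))
}

#' @export
as.data.frame.paralog_gi <- function(x, ...) x$scores

#' Score new dLFC values against a fitted screen's null models
#'
#' @param object A `"paralog_gi"` object.
#' @param newdata data.frame with columns `dlfc` and `screen` (and
#'   optionally `observed_lfc` for a ZLFC column).
#' @param ... Unused.
#' @return `newdata` with `zdlfc` (and `zlfc`) columns appended.
#' @export
predict.paralog_gi <- function(object, newdata, ...) {
  if (missing(newdata)) return(object$scores)
  stopifnot(all(c("dlfc", "screen") %in% names(newdata)))
  bad <- setdiff(unique(newdata$screen), object$screens)
  if (length(bad)) stop("unknown screen: ", bad[1L])
  newdata$zdlfc <- NA_real_
  if ("observed_lfc" %in% names(newdata)) newdata$zlfc <- NA_real_
  for (j in unique(newdata$screen)) {
    sel <- newdata$screen == j
    newdata$zdlfc[sel] <- z_dlfc(newdata$dlfc[sel], object$nulls[[j]])
    if ("observed_lfc" %in% names(newdata))
      newdata$zlfc[sel] <- z_lfc(newdata$observed_lfc[sel], object$mixtures[[j]])
  }
  newdata
}

#' Plot the dLFC distribution and fitted null per screen
#'
#' Histogram of pair dLFCs with the trimmed-Gaussian null density and
#' Tukey fences overlaid, one panel per screen.
#'
#' @param x A `"paralog_gi"` object.
#' @param screens Screens to plot (default all).
#' @param ... Passed to [graphics::hist()].
#' @export
plot.paralog_gi <- function(x, screens = x$screens, ...) {
  op <- graphics::par(mfrow = c(1, length(screens)))
  on.exit(graphics::par(op))
  for (j in screens) {
    d <- x$scores$dlfc[x$scores$screen == j]
    d <- d[is.finite(d)]
    nm <- x$nulls[[j]]
    graphics::hist(d, breaks = 50, freq = FALSE, main = j,
                   xlab = "dLFC", col = "grey85", border = "grey60", ...)
    xs <- seq(min(d), max(d), length.out = 300)
    graphics::lines(xs, stats::dnorm(xs, nm$mu, nm$sigma), col = "steelblue", lwd = 2)
    graphics::abline(v = nm$fences, lty = 2, col = "firebrick")
  }
  invisible(x)
}
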