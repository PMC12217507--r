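#' Jaccard coefficient of two hit sets
#'
#' `|A intersect B| / |A union B|`. Two empty sets have an undefined
#' ratio; it is returned as 0 with a warning.
#'
#' @param a,b Vectors treated as sets (duplicates ignored).
#' @return Numeric in \[0, 1\].
#' @export
jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0L) {
    warning("both sets empty; Jaccard coefficient undefined, returning 0")
    return(0)
  }
  length(intersect(a, b)) / u
}

#' Cross-screen consistency of hit sets
#'
#' Computes the Jaccard coefficient for every unordered pair of screens,
#' the median of those coefficients (the per-method consistency summary),
#' and the overlap spectrum: how many pairs are hit in exactly k of the n
#' screens.
#'
#' When `universes` is supplied (screen -> scoreable pair set), each
#' pairwise comparison is restricted to pairs scoreable in both screens,
#' so a pair missing from one screen's library never counts against
#' agreement.
#'
#' @param hit_sets Named list: screen -> vector of hit pair keys (>= 2
#'   screens).
#' @param universes Optional named list: screen -> scoreable pair keys.
#' @return Object of class `"gi_consistency"`: `pairwise` (data.frame
#'   `screen_a`, `screen_b`, `jaccard`), `median_jaccard`,
#'   `overlap_counts` (named integer vector, "k" -> number of pairs hit in
#'   exactly k screens), `n_screens`.
#' @export
consistency <- function(hit_sets, universes = NULL) {
  n <- length(hit_sets)
  if (n < 2L) stop("need hit sets from >= 2 screens")
  if (is.null(names(hit_sets))) names(hit_sets) <- paste0("screen", seq_len(n))
  sn <- names(hit_sets)
  cmb <- utils::combn(sn, 2L)
  jc <- apply(cmb, 2L, function(p) {
    a <- hit_sets[[p[1L]]]; b <- hit_sets[[p[2L]]]
    if (!is.null(universes)) {
      shared <- intersect(universes[[p[1L]]], universes[[p[2L]]])
      a <- intersect(a, shared); b <- intersect(b, shared)
    }
    suppressWarnings(jaccard(a, b))
  })
  pairwise <- data.frame(screen_a = cmb[1L, ], screen_b = cmb[2L, ],
                         jaccard = jc, stringsAsFactors = FALSE)
  all_hits <- unique(unlist(hit_sets, use.names = FALSE))
  k <- vapply(all_hits, function(p)
    sum(vapply(hit_sets, function(s) p %in% s, logical(1))), integer(1))
  overlap <- vapply(seq_len(n), function(i) sum(k == i), integer(1))
  names(overlap) <- as.character(seq_len(n))
  structure(list(pairwise = pairwise,
                 median_jaccard = stats::median(jc),
                 overlap_counts = overlap, n_screens = n),
            class = "gi_consistency")
}

#' @export
print.gi_consistency <- function(x, ...) {
  cat(sprintf("Hit-set consistency across %d screens\n", x$n_screens))
  cat(sprintf("  median pairwise Jaccard: %.3f\n", x$median_jaccard))
  for (i in seq_len(nrow(x$pairwise)))
    cat(sprintf("    %s vs %s: %.3f\n", x$pairwise$screen_a[i],
                x$pairwise$screen_b[i], x$pairwise$jaccard[i]))
  cat("  pairs hit in exactly k screens:\n")
  cat(sprintf("    k=%s: %d\n", names(x$overlap_counts), x$overlap_counts),
      sep = "")
  invisible(x)
}

#' Median sequence identity by hit frequency
#'
#' Stratifies the hit union by the number of screens a pair is hit in and
#' reports the median percent sequence identity per stratum. Pairs absent
#' from the identity table are skipped and counted.
#'
#' @param cons A `"gi_consistency"` object.
#' @param hit_sets The hit sets the consistency was computed from.
#' @param identity Named numeric vector (pair key -> mean percent
#'   identity), e.g. from [read_identity()].
#' @return data.frame: `k`, `n_pairs`, `n_with_identity`,
#'   `median_identity`.
#' @export
identity_by_frequency <- function(cons, hit_sets, identity) {
  all_hits <- unique(unlist(hit_sets, use.names = FALSE))
  k <- vapply(all_hits, function(p)
    sum(vapply(hit_sets, function(s) p %in% s, logical(1))), integer(1))
  out <- lapply(seq_len(cons$n_screens), function(i) {
    ps <- all_hits[k == i]
    idv <- identity[ps[ps %in% names(identity)]]
    data.frame(k = i, n_pairs = length(ps), n_with_identity = length(idv),
               median_identity = if (length(idv)) stats::median(idv) else NA_real_)
  })
  do.call(rbind, out)
}

#' Effect size between two identity strata
#'
#' Pooled-sd Cohen's D between the percent-identity distributions of two
#' hit-frequency strata (e.g. pairs hit in 3 vs 4 screens). Near-zero
#' values mean sequence similarity does not separate context-dependent
#' from pan-essential synthetic lethals.
#'
#' @param ids_a,ids_b Numeric vectors of percent identities (length >= 2).
#' @return Cohen's D (`mean(ids_a) - mean(ids_b)` over pooled sd), NA if
#'   the pooled sd is zero.
#' @export
stratum_effect_size <- function(ids_a, ids_b) cohens_d(ids_a, ids_b)

#' Fraction of cell lines expressing both genes of each pair
#'
#' A plausibility check for synthetic-lethal hits: a genuine SL pair
#' should have both members expressed in most backgrounds. Counts, per
#' pair, the fraction of expression-matrix columns where both genes exceed
#' the cut (strict >).
#'
#' @param pairs Character vector of canonical pair keys.
#' @param expr Gene x cell-line matrix of log2 TPM (see
#'   [read_expression()]).
#' @param cut Expression threshold in log2 TPM units (default 2).
#' @return data.frame: `pair`, `fraction` (NA when a member gene is
#'   missing from `expr`), `n_cell_lines`.
#' @export
expressed_fraction <- function(pairs, expr, cut = 2) {
  g <- pair_genes(pairs)
  frac <- vapply(seq_along(pairs), function(i) {
    a <- g[i, "gene_a"]; b <- g[i, "gene_b"]
    if (!(a %in% rownames(expr)) || !(b %in% rownames(expr))) return(NA_real_)
    mean(expr[a, ] > cut & expr[b, ] > cut)
  }, numeric(1))
  if (anyNA(frac))
    message(sum(is.na(frac)), " pair(s) skipped: gene missing from expression matrix")
  data.frame(pair = pairs, fraction = frac, n_cell_lines = ncol(expr),
             stringsAsFactors = FALSE)
}
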