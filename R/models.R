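#' Fit a two-component Gaussian mixture to guide-level LFCs
#'
#' Most guides in a knockout screen do not affect fitness, so the LFC
#' distribution is dominated by a tight component near zero, with a
#' lower-weight, lower-mean, wider component of fitness-defect guides. The
#' higher-weight component is taken as the null and its mean and sd
#' standardize LFCs into ZLFC (see [z_lfc()]).
#'
#' Fitting is plain EM with k-means initialization, restarted
#' `n_restarts` times from seeds derived from `seed`; the best log
#' likelihood wins, making the fit deterministic given data and seed.
#'
#' @param lfc Numeric vector of guide-level LFCs (all arrays, singles and
#'   pairs alike).
#' @param seed Integer seed for the restart initializations.
#' @param min_n Minimum number of finite values required (default 50).
#' @param n_restarts,max_iter,tol EM controls: number of random restarts
#'   (10), iteration cap (500) and relative log-likelihood convergence
#'   tolerance (1e-6).
#' @return Object of class `"gi_mixture"`: list with `weights`, `means`,
#'   `sds` (each length 2), `null_component` (index of the higher-weight
#'   component), `loglik`, `iterations`, `n`, `seed`.
#' @export
fit_lfc_mixture <- function(lfc, seed = 1L, min_n = 50L,
                            n_restarts = 10L, max_iter = 500L, tol = 1e-6) {
  x <- lfc[is.finite(lfc)]
  n <- length(x)
  if (n < min_n) stop("need >= ", min_n, " finite LFC values, got ", n)
  if (stats::sd(x) == 0) stop("degenerate LFC vector: zero variance")

  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- tryCatch(em_gauss2(x, seed = seed + r - 1L,
                              max_iter = max_iter, tol = tol),
                    error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$loglik > best$loglik)) best <- fit
  }
  if (is.null(best))
    stop("mixture fit failed to converge in ", max_iter,
         " iterations across ", n_restarts, " restarts")

  # null = higher-weight component; on an exact tie the component with the
  # larger mean (the no-effect guides sit near 0, defects below it)
  nc <- if (best$weights[1L] == best$weights[2L]) which.max(best$means)
        else which.max(best$weights)
  structure(list(weights = best$weights, means = best$means, sds = best$sds,
                 null_component = nc, loglik = best$loglik,
                 iterations = best$iterations, n = n, seed = seed),
            class = "gi_mixture")
}

# single EM run for a 2-component univariate Gaussian mixture;
# k-means initialization under the given seed
em_gauss2 <- function(x, seed, max_iter, tol) {
  n <- length(x)
  set.seed(seed)
  km <- suppressWarnings(stats::kmeans(x, centers = 2L, nstart = 1L))
  mu <- as.numeric(km$centers)
  sdv <- vapply(1:2, function(k) {
    s <- stats::sd(x[km$cluster == k])
    if (!is.finite(s) || s < 1e-8) stats::sd(x) / 2 else s
  }, numeric(1))
  w <- as.numeric(tabulate(km$cluster, 2L)) / n
  w <- pmax(w, 1e-3); w <- w / sum(w)

  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    d1 <- w[1L] * stats::dnorm(x, mu[1L], sdv[1L])
    d2 <- w[2L] * stats::dnorm(x, mu[2L], sdv[2L])
    tot <- d1 + d2
    tot[tot < .Machine$double.xmin] <- .Machine$double.xmin
    g1 <- d1 / tot
    ll <- sum(log(tot))
    n1 <- sum(g1); n2 <- n - n1
    if (n1 < 1e-8 || n2 < 1e-8) stop("component collapsed during EM")
    mu[1L] <- sum(g1 * x) / n1
    mu[2L] <- sum((1 - g1) * x) / n2
    sdv[1L] <- sqrt(sum(g1 * (x - mu[1L])^2) / n1)
    sdv[2L] <- sqrt(sum((1 - g1) * (x - mu[2L])^2) / n2)
    if (any(sdv < 1e-8)) stop("component variance collapsed during EM")
    w <- c(n1, n2) / n
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll_old) + 1))
      return(list(weights = w, means = mu, sds = sdv, loglik = ll, iterations = it))
    ll_old <- ll
  }
  stop("EM did not converge within ", max_iter, " iterations")
}

#' @export
print.gi_mixture <- function(x, ...) {
  cat("Two-component Gaussian mixture (guide-level LFC null)\n")
  for (k in 1:2) {
    cat(sprintf("  component %d: weight %.3f  mean %8.4f  sd %.4f%s\n",
                k, x$weights[k], x$means[k], x$sds[k],
                if (k == x$null_component) "   <- null" else ""))
  }
  cat(sprintf("  n = %d, log-likelihood %.2f (%d EM iterations)\n",
              x$n, x$loglik, x$iterations))
  invisible(x)
}

#' Z-transform LFCs against the mixture's null component
#'
#' `ZLFC = (LFC - mu_null) / sigma_null` where the null parameters come
#' from the higher-weight component of the screen's LFC mixture.
#'
#' @param lfc Numeric vector (guide- or target-level LFCs).
#' @param mm A `"gi_mixture"` from [fit_lfc_mixture()].
#' @return Numeric vector of ZLFC values.
#' @export
z_lfc <- function(lfc, mm) {
  stopifnot(inherits(mm, "gi_mixture"))
  k <- mm$null_component
  (lfc - mm$means[k]) / mm$sds[k]
}

#' Fit the outlier-trimmed Gaussian null to a screen's dLFC distribution
#'
#' The bulk of paralog pairs show no interaction, so the dLFC distribution
#' of a screen is well described by a single Gaussian once genuine
#' interactions (the tails) are removed. Outliers are excluded by the Tukey
#' fences Q1 - 1.5*IQR and Q3 + 1.5*IQR computed on the full vector; the
#' null mean and sd are the sample mean and sd (n-1) of the retained
#' values.
#'
#' @param dlfc Numeric vector of pair dLFC values for one screen.
#' @param min_n Minimum number of finite values (default 20).
#' @param qtype Quantile algorithm for Q1/Q3 (passed to
#'   [stats::quantile()]; default 7, linear interpolation).
#' @return Object of class `"gi_null"`: `mu`, `sigma`, `n_used`, `n_total`,
#'   `fences` (lower, upper), `q1`, `q3`.
#' @export
fit_dlfc_null <- function(dlfc, min_n = 20L, qtype = 7) {
  x <- dlfc[is.finite(dlfc)]
  if (length(x) < min_n) stop("need >= ", min_n, " finite dLFC values, got ", length(x))
  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE, type = qtype)
  iqr <- q[2L] - q[1L]
  fences <- c(lower = q[1L] - 1.5 * iqr, upper = q[2L] + 1.5 * iqr)
  keep <- x >= fences[1L] & x <= fences[2L]
  xs <- x[keep]
  if (length(xs) < 2L) stop("fewer than 2 dLFC values inside the Tukey fences")
  sigma <- stats::sd(xs)
  if (sigma == 0) stop("zero dLFC variance inside the Tukey fences; null model undefined")
  structure(list(mu = mean(xs), sigma = sigma, n_used = length(xs),
                 n_total = length(x), fences = fences,
                 q1 = q[1L], q3 = q[2L]),
            class = "gi_null")
}

#' @export
print.gi_null <- function(x, ...) {
  cat("Trimmed Gaussian dLFC null model\n")
  cat(sprintf("  mu = %.4f  sigma = %.4f\n", x$mu, x$sigma))
  cat(sprintf("  Tukey fences [%.4f, %.4f]; retained %d / %d pairs (%.1f%%)\n",
              x$fences[1L], x$fences[2L], x$n_used, x$n_total,
              100 * x$n_used / x$n_total))
  invisible(x)
}

#' Serialize / restore null-model parameters
#'
#' Writes the fitted per-screen model parameters to a small key-value text
#' file for provenance, and reads them back.
#'
#' @param mixtures,nulls Named lists (screen -> `"gi_mixture"` /
#'   `"gi_null"`).
#' @param path File path.
#' @export
write_models <- function(mixtures, nulls, path) {
  lines <- character()
  for (j in names(mixtures)) {
    mm <- mixtures[[j]]
    lines <- c(lines, sprintf(
      "mixture\t%s\tweights=%.10g,%.10g\tmeans=%.10g,%.10g\tsds=%.10g,%.10g\tnull_component=%d\tseed=%d",
      j, mm$weights[1L], mm$weights[2L], mm$means[1L], mm$means[2L],
      mm$sds[1L], mm$sds[2L], mm$null_component, mm$seed))
  }
  for (j in names(nulls)) {
    nm <- nulls[[j]]
    lines <- c(lines, sprintf(
      "dlfc_null\t%s\tmu=%.10g\tsigma=%.10g\tfences=%.10g,%.10g\tn_used=%d",
      j, nm$mu, nm$sigma, nm$fences[1L], nm$fences[2L], nm$n_used))
  }
  writeLines(lines, path)
  invisible(path)
}
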