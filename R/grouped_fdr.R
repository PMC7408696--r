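# Grouped local false discovery rate: p-values are partitioned by the
# mutated gene (biomarker) and each sufficiently large group receives its own
# null proportion pi0 and p-value density; lfdr(p) = pi0 * f0(p) / f(p) with
# a uniform theoretical null f0. Small groups fall back to the pooled density
# with pi0 forced to 1 (conservative).

#' Estimate the proportion of true null hypotheses
#'
#' Storey estimator pi0(lambda) = #\{p > lambda\} / (m * (1 - lambda)) over a
#' lambda grid, smoothed by a cubic spline and read off at the largest
#' lambda, then clamped to \[`min_pi0`, 1\].
#'
#' @param pvalues numeric vector of p-values in \[0, 1\].
#' @param lambda grid of tuning values (default 0.05 to 0.90 by 0.05).
#' @param min_pi0 lower clamp (default 0).
#' @return scalar pi0 estimate in \[0, 1\].
#' @export
estimate_pi0 <- function(pvalues, lambda = seq(0.05, 0.90, by = 0.05),
                         min_pi0 = 0) {
  if (length(pvalues) == 0) stop("no p-values")
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  m <- length(pvalues)
  pi0_l <- vapply(lambda, function(l) sum(pvalues > l) / (m * (1 - l)), 0)
  fit <- smooth.spline(lambda, pi0_l, df = 3)
  pi0 <- predict(fit, x = max(lambda))$y
  min(max(pi0, min_pi0), 1)
}

# probit-scale Gaussian KDE of the p-value density; returns the evaluation
# grid so group models can score new p-values later.
# f(p) = f_x(qnorm(p)) / dnorm(qnorm(p)), with f0 identically 1.
pdensity_fit <- function(pvalues, eps = 1e-8, adjust = 1.5) {
  p <- pmin(pmax(pvalues, eps), 1 - eps)
  x <- qnorm(p)
  if (length(unique(x)) < 2 || sd(x) == 0) {
    return(list(degenerate = TRUE, eps = eps))
  }
  d <- density(x, adjust = adjust, n = 512)
  list(degenerate = FALSE, grid_x = d$x, grid_y = d$y, eps = eps)
}

pdensity_eval <- function(fit, pvalues) {
  p <- pmin(pmax(pvalues, fit$eps), 1 - fit$eps)
  x <- qnorm(p)
  if (isTRUE(fit$degenerate)) return(rep(1, length(p)))
  fx <- approx(fit$grid_x, fit$grid_y, xout = x, rule = 2)$y
  pmax(fx, .Machine$double.xmin) / dnorm(x)
}

#' Local false discovery rate from a p-value collection
#'
#' p-values are clamped to \[eps, 1 - eps\], probit-transformed, and their
#' density is estimated by a Gaussian kernel (Silverman bandwidth, adjust
#' 1.5). The lfdr is `min(1, pi0 / f(p))` (uniform theoretical null), made
#' monotone non-decreasing in p by a running maximum over the p-sorted order.
#'
#' @param pvalues numeric vector of p-values.
#' @param pi0 proportion of true nulls (from [estimate_pi0()]).
#' @param eps clamping bound before the probit transform (default 1e-8).
#' @return list with `lfdr` (vector aligned with `pvalues`), `degenerate`
#'   flag, and the internal `density_fit`.
#' @export
lfdr_from_pvalues <- function(pvalues, pi0, eps = 1e-8) {
  if (length(pvalues) == 0) stop("no p-values")
  stopifnot(pi0 >= 0, pi0 <= 1)
  fit <- pdensity_fit(pvalues, eps = eps)
  if (fit$degenerate) {
    return(list(lfdr = rep(min(1, pi0), length(pvalues)),
                degenerate = TRUE, density_fit = fit))
  }
  f <- pdensity_eval(fit, pvalues)
  lfdr <- pmin(pi0 / f, 1)
  o <- order(pvalues)
  lfdr[o] <- cummax(lfdr[o])
  list(lfdr = lfdr, degenerate = FALSE, density_fit = fit)
}

# one group's audit/score model
new_group_model <- function(biomarker, pvalues, lfdr, pi0, fallback,
                            density_fit) {
  o <- order(pvalues)
  structure(list(biomarker = biomarker,
                 n_tests = length(pvalues),
                 pi0 = pi0,
                 fallback_used = fallback,
                 density_fit = density_fit,
                 p_sorted = pvalues[o],
                 lfdr_sorted = lfdr[o]),
            class = "group_fdr_model")
}

#' @export
print.group_fdr_model <- function(x, ...) {
  cat(sprintf("Group '%s': %d tests, pi0 = %.3f%s\n", x$biomarker, x$n_tests,
              x$pi0, if (x$fallback_used) " (pooled fallback)" else ""))
  invisible(x)
}

#' Evaluate a group lfdr model at new p-values
#'
#' Scores p-values that were not part of the original group fit: the raw
#' `min(1, pi0 / f(p))` from the stored density, floored by the largest
#' fitted lfdr at any smaller p so the monotone ordering against the fitted
#' group is preserved.
#'
#' @param model a `group_fdr_model` from [grouped_lfdr()].
#' @param pvalues p-values to score.
#' @return lfdr vector.
#' @export
predict_lfdr <- function(model, pvalues) {
  if (isTRUE(model$density_fit$degenerate)) {
    return(rep(min(1, model$pi0), length(pvalues)))
  }
  f <- pdensity_eval(model$density_fit, pvalues)
  raw <- pmin(model$pi0 / f, 1)
  floor_at <- vapply(pvalues, function(p) {
    i <- findInterval(p, model$p_sorted)
    if (i >= 1) model$lfdr_sorted[i] else 0
  }, 0)
  pmin(pmax(raw, floor_at), 1)
}

#' Grouped local FDR over a pair-test table
#'
#' Partitions p-values by biomarker gene. Groups with at least
#' `min_group_size` tests receive their own pi0 ([estimate_pi0()]) and
#' density; smaller groups are scored against the pooled all-pairs density
#' with pi0 forced to 1 and are flagged `fallback_used`.
#'
#' @param pairs data.frame with at least columns `biomarker` and `p_value`
#'   (as produced by [moderated_t_test()]).
#' @param min_group_size minimum group size for a dedicated model
#'   (default 50).
#' @return list with `lfdr` (vector aligned with `pairs` rows), `group`
#'   (biomarker per row), and `models` (named list of `group_fdr_model`).
#' @export
grouped_lfdr <- function(pairs, min_group_size = 50) {
  if (nrow(pairs) == 0) stop("no pairs")
  stopifnot(all(c("biomarker", "p_value") %in% colnames(pairs)))
  p <- pairs$p_value
  grp <- as.character(pairs$biomarker)
  lfdr <- rep(NA_real_, length(p))
  models <- list()
  pooled_fit <- NULL
  idx_by_grp <- split(seq_along(p), grp)
  for (g in names(idx_by_grp)) {
    idx <- idx_by_grp[[g]]
    if (length(idx) >= min_group_size) {
      pi0 <- estimate_pi0(p[idx])
      res <- lfdr_from_pvalues(p[idx], pi0)
      lfdr[idx] <- res$lfdr
      models[[g]] <- new_group_model(g, p[idx], res$lfdr, pi0, FALSE,
                                     res$density_fit)
    } else {
      if (is.null(pooled_fit)) pooled_fit <- pdensity_fit(p)
      if (pooled_fit$degenerate) {
        gl <- rep(1, length(idx))
      } else {
        f <- pdensity_eval(pooled_fit, p[idx])
        gl <- pmin(1 / f, 1)  # pi0 forced to 1
        o <- order(p[idx])
        gl[o] <- cummax(gl[o])
      }
      lfdr[idx] <- gl
      models[[g]] <- new_group_model(g, p[idx], gl, 1, TRUE, pooled_fit)
    }
  }
  list(lfdr = lfdr, group = grp, models = models)
}

#' Export group models as an audit table
#'
#' @param models list of `group_fdr_model` (from [grouped_lfdr()]).
#' @return data.frame with biomarker, n_tests, pi0, fallback_used.
#' @export
group_model_table <- function(models) {
  out <- data.frame(
    biomarker = vapply(models, function(m) m$biomarker, ""),
    n_tests = vapply(models, function(m) m$n_tests, 0L),
    pi0 = vapply(models, function(m) m$pi0, 0),
    fallback_used = vapply(models, function(m) m$fallback_used, FALSE),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$biomarker), , drop = FALSE]
}
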