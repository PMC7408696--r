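# Moderated two-group t-test with empirical-Bayes variance shrinkage.
#
# For one biomarker (a binary mutation vector over the cohort) every target
# row is fit as a two-group comparison MUT vs WT; the residual variances are
# then shrunk toward a common prior estimated across targets by the method of
# moments on log s2 (scaled-F hierarchical model), and the moderated t gains
# the prior degrees of freedom d0.

#' Two-group fits for every target against one mutation vector
#'
#' For each target row of the cohort essentiality matrix, computes
#' `delta_ess = mean(MUT) - mean(WT)` (negative = mutant-sensitive), the
#' pooled residual variance of the two-group model and its residual degrees
#' of freedom n' - 2.
#'
#' @param E_cohort numeric matrix, targets x cohort cell lines, no missing
#'   values.
#' @param m binary mutation vector over the cohort columns (1 = mutant).
#' @param min_group minimum size of each group (default 2); with fewer
#'   mutants or wild-types an empty fit table is returned, with the reason in
#'   attribute `skip_reason`.
#' @return data.frame with columns target, delta_ess, s2, df_residual,
#'   n_mut, n_wt.
#' @export
fit_two_group <- function(E_cohort, m, min_group = 2) {
  E_cohort <- as.matrix(E_cohort)
  if (length(m) != ncol(E_cohort)) stop("mutation vector length must match cohort size")
  if (anyNA(E_cohort)) stop("essentiality matrix has missing values; impute first")
  if (!all(m %in% c(0, 1))) stop("mutation vector must be binary")
  if (min_group < 1) {
    warning("min_group raised to 1; a single-observation group mean is a single observation")
    min_group <- 1
  }
  n_mut <- sum(m == 1)
  n_wt <- sum(m == 0)
  empty <- data.frame(target = character(), delta_ess = double(),
                      s2 = double(), df_residual = integer(),
                      n_mut = integer(), n_wt = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(E_cohort) == 0) return(empty)
  if (n_mut < min_group || n_wt < min_group) {
    attr(empty, "skip_reason") <- sprintf(
      "group too small (n_mut = %d, n_wt = %d, min_group = %d)",
      n_mut, n_wt, min_group)
    return(empty)
  }
  Em <- E_cohort[, m == 1, drop = FALSE]
  Ew <- E_cohort[, m == 0, drop = FALSE]
  mu_m <- rowMeans(Em)
  mu_w <- rowMeans(Ew)
  ss <- rowSums((Em - mu_m)^2) + rowSums((Ew - mu_w)^2)
  df <- n_mut + n_wt - 2L
  tg <- rownames(E_cohort)
  if (is.null(tg)) tg <- as.character(seq_len(nrow(E_cohort)))
  out <- data.frame(target = tg,
                    delta_ess = mu_m - mu_w,
                    s2 = if (df > 0) ss / df else NA_real_,
                    df_residual = df,
                    n_mut = n_mut, n_wt = n_wt,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# Newton solve of trigamma(x) = y, vectorized (monotone decreasing trigamma)
trigamma_inverse <- function(y) {
  x <- rep(NA_real_, length(y))
  hi <- y > 1e7
  lo <- y < 1e-6
  x[hi] <- 1 / sqrt(y[hi])
  x[lo] <- 1 / y[lo]
  mid <- !hi & !lo
  if (any(mid)) {
    z <- 0.5 + 1 / y[mid]
    for (iter in 1:50) {
      tri <- trigamma(z)
      dif <- tri * (1 - tri / y[mid]) / psigamma(z, deriv = 2)
      z <- z + dif
      if (max(abs(dif / z)) < 1e-10) break
    }
    x[mid] <- z
  }
  x
}

#' Estimate the variance prior across targets
#'
#' Method-of-moments fit on log s2: under the hierarchical model the residual
#' variances follow a scaled F distribution, so the excess dispersion of
#' log s2 over the trigamma(df/2) expected under equal true variances
#' identifies the prior degrees of freedom d0, and the centred mean of log s2
#' identifies the prior variance s0_sq. When the observed dispersion does not
#' exceed the sampling expectation, d0 is infinite (all true variances
#' equal). Zero variances participate through a small offset (smallest
#' positive s2 times 1e-6).
#'
#' @param s2 vector of residual variances.
#' @param df residual degrees of freedom (scalar or vector).
#' @return list of class `variance_prior` with `d0` (possibly `Inf`) and
#'   `s0_sq`.
#' @export
estimate_variance_prior <- function(s2, df) {
  df <- rep_len(df, length(s2))
  keep <- is.finite(s2) & s2 >= 0 & is.finite(df) & df > 0
  s2 <- s2[keep]
  df <- df[keep]
  if (length(s2) < 2) {
    # not enough targets to learn a prior: no shrinkage
    return(structure(list(d0 = 0, s0_sq = NA_real_), class = "variance_prior"))
  }
  if (all(s2 == 0)) stop("all residual variances are zero; degenerate data")
  if (any(s2 == 0)) {
    off <- min(s2[s2 > 0]) * 1e-6
    message(sum(s2 == 0), " zero variance(s) offset by ", signif(off, 3),
            " for prior estimation")
    s2[s2 == 0] <- off
  }
  e <- log(s2) - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- var(e) - mean(trigamma(df / 2))
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_sq <- exp(emean)
  }
  structure(list(d0 = d0, s0_sq = s0_sq), class = "variance_prior")
}

#' @export
print.variance_prior <- function(x, ...) {
  cat(sprintf("Variance prior: d0 = %s, s0_sq = %s\n",
              format(x$d0), format(x$s0_sq)))
  invisible(x)
}

#' Moderated t-test from two-group fits and a variance prior
#'
#' Posterior variances `s2_post = (d0 * s0_sq + df * s2) / (d0 + df)` shrink
#' each target's residual variance toward the prior; the moderated t is
#' `delta_ess / sqrt(s2_post * (1/n_mut + 1/n_wt))` on `d0 + df` degrees of
#' freedom, two-sided (normal when d0 is infinite). With `d0 = 0` this is
#' the ordinary pooled two-sample t-test.
#'
#' @param fits data.frame from [fit_two_group()].
#' @param prior list with `d0`, `s0_sq` from [estimate_variance_prior()].
#' @param biomarker optional biomarker symbol recorded in the output.
#' @return data.frame with columns target, biomarker, delta_ess, t_moderated,
#'   p_value, df_total, n_mut, n_wt, degenerate.
#' @export
moderated_t_test <- function(fits, prior, biomarker = NA_character_) {
  if (nrow(fits) == 0) stop("no fits to test")
  d0 <- prior$d0
  s0 <- prior$s0_sq
  df <- fits$df_residual
  if (is.infinite(d0)) {
    s2_post <- rep(s0, nrow(fits))
    df_total <- rep(Inf, nrow(fits))
  } else if (d0 == 0) {
    s2_post <- fits$s2
    df_total <- df
  } else {
    s2_post <- (d0 * s0 + df * fits$s2) / (d0 + df)
    df_total <- d0 + df
  }
  se2 <- s2_post * (1 / fits$n_mut + 1 / fits$n_wt)
  degenerate <- se2 <= 0
  tmod <- ifelse(degenerate, ifelse(fits$delta_ess == 0, 0, sign(fits$delta_ess) * Inf),
                 fits$delta_ess / sqrt(pmax(se2, .Machine$double.xmin)))
  p <- ifelse(is.infinite(df_total),
              2 * pnorm(-abs(tmod)),
              2 * pt(-abs(tmod), df = df_total))
  p[degenerate & fits$delta_ess != 0] <- 0
  p[degenerate & fits$delta_ess == 0] <- 1
  data.frame(target = fits$target,
             biomarker = biomarker,
             delta_ess = fits$delta_ess,
             t_moderated = tmod,
             p_value = pmin(pmax(p, 0), 1),
             df_total = df_total,
             n_mut = fits$n_mut,
             n_wt = fits$n_wt,
             degenerate = degenerate,
             stringsAsFactors = FALSE)
}
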