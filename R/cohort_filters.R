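# Cohort selection and the three target pre-filters: essentiality prevalence
# in the cohort, cohort specificity (odds ratio), and minimum expression.

#' Select an analysis cohort from the panel annotation
#'
#' Either all lines annotated with `tumor_type`, or an explicit list of
#' cell-line ids. The complement is every other annotated panel line.
#'
#' @param ann annotation data.frame (`cellline_id`, `tumor_type`).
#' @param tumor_type tumor-type label to select.
#' @param id_list explicit cell-line ids (alternative to `tumor_type`).
#' @return A `cohort` object: list with `name`, `member_ids`, `complement_ids`.
#' @export
select_cohort <- function(ann, tumor_type = NULL, id_list = NULL) {
  panel <- ann$cellline_id
  if (!is.null(tumor_type)) {
    members <- panel[ann$tumor_type == tumor_type]
    if (length(members) == 0) {
      stop("no cell lines annotated with tumor type '", tumor_type, "'")
    }
    name <- tumor_type
  } else if (!is.null(id_list)) {
    missing <- setdiff(id_list, panel)
    if (length(missing)) {
      stop("cell line(s) not in panel: ", paste(missing, collapse = ", "))
    }
    if (length(id_list) == 0) stop("empty cohort")
    members <- id_list
    name <- "custom"
  } else {
    stop("supply either tumor_type or id_list")
  }
  structure(list(name = name,
                 member_ids = members,
                 complement_ids = setdiff(panel, members)),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Cohort '%s': %d member lines, %d complement lines\n",
              x$name, length(x$member_ids), length(x$complement_ids)))
  invisible(x)
}

#' Fraction of lines in which a target is essential
#'
#' Essential means the score is strictly below the cutoff (more negative =
#' more essential).
#'
#' @param scores numeric vector of essentiality scores (no missing values).
#' @param cutoff essentiality threshold (default -2).
#' @return fraction in \[0, 1\].
#' @export
essential_fraction <- function(scores, cutoff = -2) {
  if (length(scores) == 0) stop("empty score vector")
  if (anyNA(scores)) stop("scores contain missing values; impute first")
  mean(scores < cutoff)
}

# odds ratio from a 2x2 table, Haldane-Anscombe +0.5 applied iff any cell is 0
haldane_or <- function(a, b, c, d) {
  if (min(a, b, c, d) < 0) stop("negative cell count")
  if (min(a, b, c, d) == 0) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  (a * d) / (b * c)
}

#' Cohort-specificity statistics for one target
#'
#' Builds the 2x2 essential/non-essential by cohort/complement table and
#' returns the odds ratio (Haldane-Anscombe corrected only when a cell is
#' zero) and the essential fraction among complement lines.
#'
#' @param target_scores named numeric vector of scores over the full panel.
#' @param cohort a [select_cohort()] result.
#' @param cutoff essentiality threshold (default -2).
#' @return list with `odds_ratio`, `other_fraction`, and the 2x2 counts
#'   `a` (cohort essential), `b` (cohort non-essential), `c` (other
#'   essential), `d` (other non-essential).
#' @export
specificity_stats <- function(target_scores, cohort, cutoff = -2) {
  if (length(cohort$member_ids) == 0 || length(cohort$complement_ids) == 0) {
    stop("cohort and complement must both be non-empty")
  }
  ess <- target_scores < cutoff
  a <- sum(ess[cohort$member_ids])
  b <- length(cohort$member_ids) - a
  c <- sum(ess[cohort$complement_ids])
  d <- length(cohort$complement_ids) - c
  list(odds_ratio = haldane_or(a, b, c, d),
       other_fraction = c / (c + d),
       a = a, b = b, c = c, d = d)
}

#' Fraction of cohort lines expressing a gene
#'
#' @param tpm numeric TPM vector over the cohort.
#' @param min_tpm inclusive expression threshold (default 1 TPM).
#' @return fraction of lines with TPM >= `min_tpm`.
#' @export
expressed_fraction <- function(tpm, min_tpm = 1) {
  if (length(tpm) == 0) stop("empty TPM vector")
  mean(tpm >= min_tpm)
}

#' Pre-filter parameters
#'
#' Defaults encode the screening thresholds: essential (score < -2) in more
#' than 20% of cohort lines; specific to the cohort (odds ratio > 1 and
#' essential in at most 20% of other lines); expressed (>= 1 TPM) in more
#' than 75% of cohort lines. ">" thresholds are strict, "at most" and the
#' TPM floor are inclusive.
#'
#' @param essentiality_cutoff score below which a gene counts as essential.
#' @param min_cohort_essential_fraction strict lower bound on the cohort
#'   essential fraction.
#' @param max_other_essential_fraction inclusive upper bound on the
#'   complement essential fraction.
#' @param require_odds_ratio_gt strict lower bound on the specificity odds
#'   ratio.
#' @param min_tpm inclusive TPM floor for "expressed".
#' @param min_expressed_fraction strict lower bound on the expressed fraction.
#' @return list of class `filter_params`.
#' @export
filter_params <- function(essentiality_cutoff = -2,
                          min_cohort_essential_fraction = 0.20,
                          max_other_essential_fraction = 0.20,
                          require_odds_ratio_gt = 1,
                          min_tpm = 1,
                          min_expressed_fraction = 0.75) {
  p <- list(essentiality_cutoff = essentiality_cutoff,
            min_cohort_essential_fraction = min_cohort_essential_fraction,
            max_other_essential_fraction = max_other_essential_fraction,
            require_odds_ratio_gt = require_odds_ratio_gt,
            min_tpm = min_tpm,
            min_expressed_fraction = min_expressed_fraction)
  fr <- c(p$min_cohort_essential_fraction, p$max_other_essential_fraction,
          p$min_expressed_fraction)
  if (any(fr < 0 | fr > 1)) stop("fraction thresholds must lie in [0, 1]")
  if (!is.finite(p$essentiality_cutoff)) stop("essentiality_cutoff must be finite")
  structure(p, class = "filter_params")
}

#' Apply the three target pre-filters over a cohort
#'
#' A target passes overall iff its cohort essential fraction exceeds
#' `min_cohort_essential_fraction` (strict), its specificity odds ratio
#' exceeds `require_odds_ratio_gt` (strict), its complement essential
#' fraction is at most `max_other_essential_fraction`, and its expressed
#' fraction exceeds `min_expressed_fraction` (strict). Targets absent from
#' the expression matrix fail the expression criterion.
#'
#' @param E imputed [essentiality_matrix()] over the full panel.
#' @param X expression matrix (TPM) over the panel.
#' @param cohort a [select_cohort()] result.
#' @param params a [filter_params()] object.
#' @return data.frame (class `target_filter_report`) with one row per target:
#'   the per-criterion statistics, pass flags and overall `pass`.
#' @export
target_prefilter <- function(E, X, cohort, params = filter_params()) {
  stopifnot(inherits(E, "ess_matrix"))
  if (any(E$missing_mask)) stop("essentiality matrix has missing values; run impute_knn() first")
  V <- E$values
  mem <- cohort$member_ids
  oth <- cohort$complement_ids
  if (!all(c(mem, oth) %in% colnames(V))) {
    stop("cohort cell lines missing from the essentiality matrix")
  }
  ess <- V < params$essentiality_cutoff
  a <- rowSums(ess[, mem, drop = FALSE])
  c_ <- rowSums(ess[, oth, drop = FALSE])
  b <- length(mem) - a
  d <- length(oth) - c_
  coh_frac <- a / length(mem)
  oth_frac <- c_ / length(oth)
  or <- mapply(haldane_or, a, b, c_, d)

  in_expr <- rownames(V) %in% rownames(X)
  if (!all(in_expr)) {
    message(sum(!in_expr), " target(s) absent from the expression matrix fail the expression filter")
  }
  expr_frac <- rep(0, nrow(V))
  idx <- match(rownames(V)[in_expr], rownames(X))
  expr_frac[in_expr] <- rowMeans(X[idx, mem, drop = FALSE] >= params$min_tpm)

  pass_ess <- coh_frac > params$min_cohort_essential_fraction
  pass_spec <- (or > params$require_odds_ratio_gt) &
    (oth_frac <= params$max_other_essential_fraction)
  pass_expr <- expr_frac > params$min_expressed_fraction
  rep_ <- data.frame(
    target = rownames(V),
    cohort_essential_fraction = coh_frac,
    other_essential_fraction = oth_frac,
    odds_ratio = or,
    expressed_fraction = expr_frac,
    pass_essential = pass_ess,
    pass_specific = pass_spec,
    pass_expressed = pass_expr,
    pass = pass_ess & pass_spec & pass_expr,
    stringsAsFactors = FALSE)
  rownames(rep_) <- NULL
  class(rep_) <- c("target_filter_report", "data.frame")
  rep_
}

#' Write a target filter report as TSV
#'
#' @param report a [target_prefilter()] result.
#' @param path output file path.
#' @export
write_filter_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
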