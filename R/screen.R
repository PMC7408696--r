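# End-to-end screen: prefilter targets, test every (target, biomarker) pair,
# correct by grouped lfdr, threshold, attach drugs and interaction evidence,
# and rank. Also the case-by-case single-pair test and mutation co-occurrence.

#' Screen parameters
#'
#' @param filter a [filter_params()] object (the three target pre-filters).
#' @param max_lfdr keep pairs with lfdr at or below this (default 0.5).
#' @param min_abs_delta_ess keep pairs with |delta_ess| at least this many
#'   score units (default 2); applied as a magnitude gate in both directions.
#' @param require_interaction if TRUE, keep only pairs whose (target,
#'   biomarker) is in the supplied interaction set (default FALSE: the flag
#'   is annotated only).
#' @param min_group minimum mutant and wild-type group size for a pair to be
#'   testable (default 2).
#' @param min_group_size_lfdr minimum biomarker-group size for a dedicated
#'   lfdr model (default 50).
#' @param prior_scope "biomarker" (one variance prior per mutation vector,
#'   the default) or "global" (a single prior across all pairs).
#' @return list of class `screen_params`.
#' @export
screen_params <- function(filter = filter_params(),
                          max_lfdr = 0.5,
                          min_abs_delta_ess = 2,
                          require_interaction = FALSE,
                          min_group = 2,
                          min_group_size_lfdr = 50,
                          prior_scope = c("biomarker", "global")) {
  prior_scope <- match.arg(prior_scope)
  if (max_lfdr <= 0 || max_lfdr > 1) stop("max_lfdr must lie in (0, 1]")
  if (min_abs_delta_ess < 0) stop("min_abs_delta_ess must be non-negative")
  structure(list(filter = filter, max_lfdr = max_lfdr,
                 min_abs_delta_ess = min_abs_delta_ess,
                 require_interaction = require_interaction,
                 min_group = min_group,
                 min_group_size_lfdr = min_group_size_lfdr,
                 prior_scope = prior_scope),
            class = "screen_params")
}

#' Map targets to the drugs that inhibit them
#'
#' Exact symbol match against the DTI table; drug lists are deduplicated and
#' sorted so the mapping is deterministic. Targets without any drug map to an
#' empty vector (such pairs are still reported by the screen).
#'
#' @param targets character vector of target symbols.
#' @param dti drug-target table (see [read_dti()]); may be NULL.
#' @return named list, target -> character vector of drug ids.
#' @export
map_targets_to_drugs <- function(targets, dti) {
  out <- setNames(vector("list", length(targets)), targets)
  for (tg in targets) {
    out[[tg]] <- if (is.null(dti)) character(0) else
      sort(unique(dti$drug_id[dti$target == tg]))
  }
  out
}

# canonical unordered key for a gene pair
pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

#' Filter or annotate pairs by gene-gene interaction support
#'
#' Membership of the unordered \{target, biomarker\} pair in the interaction
#' set. With `require_interaction`, non-supported pairs are dropped;
#' otherwise only the `interaction_supported` column is set.
#'
#' @param pairs data.frame with `target` and `biomarker` columns.
#' @param interactions data.frame with `gene1`, `gene2` columns (unordered
#'   pairs); may be NULL (no support anywhere).
#' @param require_interaction drop unsupported pairs (default FALSE).
#' @return the annotated (and possibly filtered) data.frame.
#' @export
interaction_filter <- function(pairs, interactions, require_interaction = FALSE) {
  keys <- if (is.null(interactions) || nrow(interactions) == 0) character(0) else
    pair_key(interactions$gene1, interactions$gene2)
  pairs$interaction_supported <- pair_key(pairs$target, pairs$biomarker) %in% keys
  if (require_interaction) {
    pairs <- pairs[pairs$interaction_supported, , drop = FALSE]
    rownames(pairs) <- NULL
  }
  pairs
}

#' Mutation co-occurrence of one gene against all others in the cohort
#'
#' For each other gene in the cohort mutation matrix, the 2x2 mutant/wild-type
#' cross table against `gene`, the Haldane-corrected odds ratio and the
#' two-sided Fisher exact p-value, sorted by p ascending.
#'
#' @param M_cohort binary mutation matrix restricted to the cohort columns.
#' @param gene biomarker gene to cross against.
#' @return data.frame: gene, n11, n10, n01, n00, odds_ratio, p_value.
#' @export
mutation_cooccurrence <- function(M_cohort, gene) {
  if (!gene %in% rownames(M_cohort)) stop("gene '", gene, "' not in the mutation matrix")
  if (ncol(M_cohort) < 4) stop("cohort too small for co-occurrence testing (need >= 4 lines)")
  g <- M_cohort[gene, ]
  others <- setdiff(rownames(M_cohort), gene)
  res <- lapply(others, function(o) {
    v <- M_cohort[o, ]
    n11 <- sum(g == 1 & v == 1); n10 <- sum(g == 1 & v == 0)
    n01 <- sum(g == 0 & v == 1); n00 <- sum(g == 0 & v == 0)
    p <- fisher.test(matrix(c(n11, n10, n01, n00), 2, byrow = TRUE))$p.value
    data.frame(gene = o, n11 = n11, n10 = n10, n01 = n01, n00 = n00,
               odds_ratio = haldane_or(n11, n10, n01, n00), p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- out[order(out$p_value, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Fit and test every (prefiltered target) x (eligible biomarker) pair and
# attach the grouped lfdr; query restriction happens afterwards so the lfdr
# model never depends on the query.
build_screen_model <- function(bundle, cohort, params) {
  E <- bundle$essentiality
  if (any(E$missing_mask)) stop("essentiality matrix has missing values; run impute_knn() first")
  report <- target_prefilter(E, bundle$expression, cohort, params$filter)
  kept <- report$target[report$pass]
  Ec <- E$values[, cohort$member_ids, drop = FALSE]
  M <- bundle$mutation
  mut_counts <- rowSums(M[, cohort$member_ids, drop = FALSE])
  n_cohort <- length(cohort$member_ids)
  eligible <- rownames(M)[mut_counts >= params$min_group &
                            (n_cohort - mut_counts) >= params$min_group]
  skipped <- setdiff(rownames(M), eligible)

  fits_by_bm <- list()
  for (bm in eligible) {
    f <- fit_two_group(Ec[kept, , drop = FALSE],
                       M[bm, cohort$member_ids], min_group = params$min_group)
    if (nrow(f)) fits_by_bm[[bm]] <- f
  }

  pairs <- NULL
  priors <- list()
  if (length(fits_by_bm)) {
    global_prior <- NULL
    if (params$prior_scope == "global" ||
        any(vapply(fits_by_bm, nrow, 0L) < 2)) {
      all_s2 <- unlist(lapply(fits_by_bm, `[[`, "s2"))
      all_df <- unlist(lapply(fits_by_bm, `[[`, "df_residual"))
      global_prior <- estimate_variance_prior(all_s2, all_df)
    }
    tested <- lapply(names(fits_by_bm), function(bm) {
      f <- fits_by_bm[[bm]]
      prior <- if (params$prior_scope == "biomarker" && nrow(f) >= 2) {
        estimate_variance_prior(f$s2, f$df_residual)
      } else global_prior
      priors[[bm]] <<- prior
      moderated_t_test(f, prior, biomarker = bm)
    })
    pairs <- do.call(rbind, tested)
    rownames(pairs) <- NULL
  }

  lfdr_models <- NULL
  if (!is.null(pairs) && nrow(pairs)) {
    gl <- grouped_lfdr(pairs, min_group_size = params$min_group_size_lfdr)
    pairs$lfdr <- gl$lfdr
    lfdr_models <- gl$models
  }
  list(report = report, kept_targets = kept, eligible_biomarkers = eligible,
       skipped_biomarkers = skipped, pairs = pairs, priors = priors,
       lfdr_models = lfdr_models, cohort = cohort)
}

rank_pairs <- function(pairs) {
  o <- order(pairs$lfdr, pairs$p_value, -abs(pairs$delta_ess),
             pairs$target, pairs$biomarker)
  pairs <- pairs[o, , drop = FALSE]
  rownames(pairs) <- NULL
  pairs
}

#' Run the end-to-end biomarker screen
#'
#' Pipeline: target pre-filters over the cohort; moderated t-tests for every
#' (prefiltered target, eligible biomarker) pair; grouped lfdr over all
#' tested pairs (by biomarker); query restriction; lfdr and |delta_ess|
#' thresholds; drug and interaction annotation; total deterministic ranking
#' (lfdr, then p, then |delta_ess| descending, then lexicographic).
#'
#' The lfdr model is always computed over the full tested-pair set before
#' any query restriction, so restricted queries return exactly the matching
#' subset of the mode = "all" result.
#'
#' @param bundle an aligned `screen_bundle` (see [align_panel()] or
#'   [generate_bundle()]).
#' @param cohort a [select_cohort()] result.
#' @param params a [screen_params()] object.
#' @param mode one of "all", "targets", "drugs", "mutations".
#' @param items query symbols / drug ids (empty iff `mode = "all"`).
#' @return data.frame of class `ranked_pairs` with columns target, biomarker,
#'   delta_ess, t_moderated, p_value, lfdr, n_mut, n_wt, direction, drugs
#'   (comma-separated), interaction_supported; attributes `manifest`,
#'   `report`, `model`.
#' @export
run_screen <- function(bundle, cohort, params = screen_params(),
                       mode = c("all", "targets", "drugs", "mutations"),
                       items = character(0)) {
  mode <- match.arg(mode)
  if (mode == "all" && length(items)) stop("items must be empty for mode = 'all'")
  if (mode != "all" && !length(items)) stop("mode '", mode, "' requires items")

  # validate query items against their universe up front
  if (mode == "targets") {
    missing <- setdiff(items, rownames(bundle$essentiality$values))
    if (length(missing)) stop("target(s) not in essentiality matrix: ",
                              paste(missing, collapse = ", "))
  } else if (mode == "mutations") {
    missing <- setdiff(items, rownames(bundle$mutation))
    if (length(missing)) stop("mutation gene(s) not in mutation matrix: ",
                              paste(missing, collapse = ", "))
  } else if (mode == "drugs") {
    if (is.null(bundle$dti)) stop("mode 'drugs' requires a DTI table in the bundle")
    missing <- setdiff(items, bundle$dti$drug_id)
    if (length(missing)) stop("drug(s) not in DTI table: ",
                              paste(missing, collapse = ", "))
  }

  model <- build_screen_model(bundle, cohort, params)
  pairs <- model$pairs
  empty <- data.frame(target = character(), biomarker = character(),
                      delta_ess = double(), t_moderated = double(),
                      p_value = double(), lfdr = double(),
                      n_mut = integer(), n_wt = integer(),
                      direction = character(), drugs = character(),
                      interaction_supported = logical(),
                      stringsAsFactors = FALSE)
  if (is.null(pairs) || nrow(pairs) == 0) {
    warning("no testable (target, biomarker) pairs for this cohort/query")
    pairs <- empty
  } else {
    # query restriction after the full model
    if (mode == "targets") {
      pairs <- pairs[pairs$target %in% items, , drop = FALSE]
    } else if (mode == "mutations") {
      pairs <- pairs[pairs$biomarker %in% items, , drop = FALSE]
    } else if (mode == "drugs") {
      qt <- unique(bundle$dti$target[bundle$dti$drug_id %in% items])
      pairs <- pairs[pairs$target %in% qt, , drop = FALSE]
    }
    pairs <- pairs[pairs$lfdr <= params$max_lfdr &
                     abs(pairs$delta_ess) >= params$min_abs_delta_ess, ,
                   drop = FALSE]
  }
  if (nrow(pairs)) {
    pairs$direction <- ifelse(pairs$delta_ess < 0, "mutant-sensitive",
                              "mutant-resistant")
    drug_map <- map_targets_to_drugs(unique(pairs$target), bundle$dti)
    pairs$drugs <- vapply(pairs$target,
                          function(tg) paste(drug_map[[tg]], collapse = ","), "")
    pairs <- interaction_filter(pairs, bundle$interactions,
                                params$require_interaction)
    pairs$degenerate <- NULL
    pairs$df_total <- NULL
    pairs <- rank_pairs(pairs)
  } else {
    pairs <- empty
  }
  manifest <- list(
    mode = mode, items = items, cohort = cohort$name,
    n_cohort = length(cohort$member_ids),
    n_complement = length(cohort$complement_ids),
    n_prefiltered_targets = length(model$kept_targets),
    n_eligible_biomarkers = length(model$eligible_biomarkers),
    n_tested_pairs = if (is.null(model$pairs)) 0L else nrow(model$pairs),
    n_reported_pairs = nrow(pairs),
    params = unclass_params(params))
  attr(pairs, "manifest") <- manifest
  attr(pairs, "report") <- model$report
  attr(pairs, "model") <- model
  class(pairs) <- c("ranked_pairs", "data.frame")
  pairs
}

unclass_params <- function(params) {
  p <- unclass(params)
  p$filter <- unclass(p$filter)
  p
}

#' @export
print.ranked_pairs <- function(x, n = 10, ...) {
  man <- attr(x, "manifest")
  cat(sprintf("Ranked pairs: %d reported of %d tested (cohort '%s', mode '%s')\n",
              man$n_reported_pairs, man$n_tested_pairs, man$cohort, man$mode))
  print.data.frame(head(as.data.frame(x), n))
  invisible(x)
}

#' Case-by-case test of a single (target, biomarker) pair
#'
#' Statistics are computed exactly as in the screen but without the target
#' pre-filters or thresholds, so pairs eliminated by the screening battery
#' can still be assessed. When the pair is part of the full-screen model its
#' row is returned verbatim; when only the target was filtered out, it is fit
#' with the biomarker's screen prior and scored against that biomarker's
#' stored lfdr model; when the biomarker has no screen group at all, the
#' group model is built on demand from all targets against that biomarker.
#'
#' @param bundle an aligned `screen_bundle`.
#' @param cohort a [select_cohort()] result.
#' @param target target gene symbol (row of the essentiality matrix).
#' @param biomarker mutation gene symbol (row of the mutation matrix).
#' @param params a [screen_params()] object.
#' @return one-row data.frame: target, biomarker, delta_ess, t_moderated,
#'   p_value, lfdr, n_mut, n_wt, direction, in_screen_model.
#' @export
test_pair <- function(bundle, cohort, target, biomarker,
                      params = screen_params()) {
  E <- bundle$essentiality
  if (!target %in% rownames(E$values)) stop("target '", target, "' not in essentiality matrix")
  if (!biomarker %in% rownames(bundle$mutation)) stop("biomarker '", biomarker, "' not in mutation matrix")
  m <- bundle$mutation[biomarker, cohort$member_ids]
  n_mut <- sum(m == 1); n_wt <- sum(m == 0)
  if (n_mut < params$min_group || n_wt < params$min_group) {
    stop("group too small (n_mut = ", n_mut, ", n_wt = ", n_wt,
         ", min_group = ", params$min_group, ")")
  }
  model <- build_screen_model(bundle, cohort, params)
  Ec <- E$values[, cohort$member_ids, drop = FALSE]

  if (!is.null(model$pairs)) {
    hit <- model$pairs[model$pairs$target == target &
                         model$pairs$biomarker == biomarker, , drop = FALSE]
    if (nrow(hit) == 1) {
      out <- hit[, c("target", "biomarker", "delta_ess", "t_moderated",
                     "p_value", "lfdr", "n_mut", "n_wt")]
      out$direction <- ifelse(out$delta_ess < 0, "mutant-sensitive", "mutant-resistant")
      out$in_screen_model <- TRUE
      rownames(out) <- NULL
      return(out)
    }
  }

  if (!is.null(model$lfdr_models) && biomarker %in% names(model$lfdr_models)) {
    # target failed the prefilter: reuse the biomarker's screen prior + model
    fit <- fit_two_group(Ec[target, , drop = FALSE], m,
                         min_group = params$min_group)
    pt_ <- moderated_t_test(fit, model$priors[[biomarker]], biomarker)
    lfdr <- predict_lfdr(model$lfdr_models[[biomarker]], pt_$p_value)
  } else {
    # biomarker absent from the screen model: build it from all targets
    fit_all <- fit_two_group(Ec, m, min_group = params$min_group)
    prior <- estimate_variance_prior(fit_all$s2, fit_all$df_residual)
    tests <- moderated_t_test(fit_all, prior, biomarker)
    gl <- grouped_lfdr(tests, min_group_size = params$min_group_size_lfdr)
    i <- which(tests$target == target)
    pt_ <- tests[i, , drop = FALSE]
    lfdr <- gl$lfdr[i]
  }
  out <- data.frame(target = target, biomarker = biomarker,
                    delta_ess = pt_$delta_ess, t_moderated = pt_$t_moderated,
                    p_value = pt_$p_value, lfdr = lfdr,
                    n_mut = n_mut, n_wt = n_wt,
                    direction = ifelse(pt_$delta_ess < 0, "mutant-sensitive",
                                       "mutant-resistant"),
                    in_screen_model = FALSE,
                    stringsAsFactors = FALSE)
  out
}

#' Write a ranked-pairs table as TSV plus a JSON run manifest
#'
#' Numeric columns are serialized with full precision (`format(..., digits =
#' 15)`), so identical results give byte-identical files.
#'
#' @param pairs a [run_screen()] result.
#' @param path output TSV path; the manifest goes to `<path>.manifest.json`.
#' @param seed optional integer recorded in the manifest.
#' @return `path`, invisibly.
#' @export
write_ranked_pairs <- function(pairs, path, seed = NULL) {
  df <- as.data.frame(pairs)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) format(x, digits = 15, trim = TRUE,
                                                scientific = NA))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  man <- attr(pairs, "manifest")
  man$seed <- seed
  jsonlite::write_json(man, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}
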