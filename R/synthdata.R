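# Synthetic input bundles with known ground truth: panel-scale essentiality,
# mutation, expression, annotation, DTI and interaction tables emulating the
# shapes of RNAi-dependency / cell-line-panel data at reduced scale.

#' Configuration for the synthetic bundle generator
#'
#' Defaults emulate a 400-line panel containing a 22-line tumor cohort,
#' 500 knockdown targets and 40 mutated biomarker genes with per-gene
#' mutation frequencies between 5% and 50%, unit-variance Gaussian score
#' noise around per-target baselines, and no missing entries.
#'
#' @param n_panel number of panel cell lines (default 400).
#' @param n_cohort cohort size; the first `n_cohort` lines form the cohort
#'   (default 22).
#' @param n_targets number of knockdown targets (default 500).
#' @param n_biomarkers number of mutated genes (default 40).
#' @param mutation_freq_range per-gene mutation frequency range
#'   (default c(0.05, 0.5)).
#' @param base_score_mean grand mean of the essentiality scores (default 0).
#' @param target_effect_sd SD of per-target baseline offsets, giving genes
#'   different overall essentiality (default 0: scores are noise around the
#'   grand mean plus planted/background shifts). Set positive to emulate
#'   row-correlated panels, e.g. when exercising neighbour-based imputation.
#' @param noise_sd residual score SD (default 1).
#' @param planted list of planted associations; each element a list with
#'   `target`, `biomarker`, `delta` (score shift added to mutant lines),
#'   optional `cohort_only` (default TRUE) and optional `n_mut` (exact
#'   number of mutant cohort lines; otherwise Bernoulli at the gene's
#'   frequency).
#' @param essential_background list of panel-wide essential distractors;
#'   each a list with `target` and `shift` (added to every line).
#' @param missing_rate fraction of essentiality entries masked as missing
#'   (default 0).
#' @param low_expression_fraction fraction of targets forced to low TPM so
#'   the expression filter has work to do (default 0.10); planted targets
#'   are never chosen.
#' @param n_decoy_interactions random decoy gene pairs added to the
#'   interaction set alongside all planted pairs (default 100).
#' @param seed integer RNG seed.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_panel = 400, n_cohort = 22, n_targets = 500,
                             n_biomarkers = 40,
                             mutation_freq_range = c(0.05, 0.5),
                             base_score_mean = 0, target_effect_sd = 0,
                             noise_sd = 1, planted = list(),
                             essential_background = list(),
                             missing_rate = 0,
                             low_expression_fraction = 0.10,
                             n_decoy_interactions = 100,
                             seed = 1) {
  cfg <- list(n_panel = n_panel, n_cohort = n_cohort, n_targets = n_targets,
              n_biomarkers = n_biomarkers,
              mutation_freq_range = mutation_freq_range,
              base_score_mean = base_score_mean,
              target_effect_sd = target_effect_sd,
              noise_sd = noise_sd, planted = planted,
              essential_background = essential_background,
              missing_rate = missing_rate,
              low_expression_fraction = low_expression_fraction,
              n_decoy_interactions = n_decoy_interactions,
              seed = seed)
  if (cfg$n_cohort > cfg$n_panel) stop("n_cohort must not exceed n_panel")
  if (cfg$n_cohort < 1 || cfg$n_panel < 3) stop("panel too small")
  if (cfg$noise_sd <= 0) stop("noise_sd must be positive")
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1) stop("missing_rate must lie in [0, 1)")
  fr <- cfg$mutation_freq_range
  if (length(fr) != 2 || any(fr <= 0) || any(fr >= 1) || fr[1] > fr[2]) {
    stop("mutation_freq_range must be increasing within (0, 1)")
  }
  tg_ids <- sprintf("T%03d", seq_len(cfg$n_targets))
  bm_ids <- sprintf("B%03d", seq_len(cfg$n_biomarkers))
  for (pl in cfg$planted) {
    if (!pl$target %in% tg_ids) stop("planted target out of range: ", pl$target)
    if (!pl$biomarker %in% bm_ids) stop("planted biomarker out of range: ", pl$biomarker)
    if (!is.null(pl$n_mut) && pl$n_mut > cfg$n_cohort) {
      stop("planted n_mut exceeds cohort size")
    }
  }
  structure(cfg, class = "synthetic_config")
}

#' Generate a synthetic aligned bundle with ground truth
#'
#' Mutation status is Bernoulli per gene and line; essentiality scores are
#' Gaussian around per-target baselines with planted shifts added to mutant
#' lines of planted pairs (cohort lines only when `cohort_only`); expression
#' is log-normal with a configurable fraction of targets forced below 1 TPM
#' in most cohort lines; missing essentiality entries are masked at
#' `missing_rate`; the DTI table assigns 0-3 fictitious drugs per target and
#' the interaction set holds all planted pairs plus random decoys. Fully
#' reproducible from the seed.
#'
#' @param config a [synthetic_config()] object.
#' @return list with `bundle` (a `screen_bundle`, already aligned), `cohort`
#'   (a `cohort` object) and `truth` (planted list plus realized mutation
#'   counts and realized delta_ess per planted pair).
#' @export
generate_bundle <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_panel
  lines <- sprintf("L%04d", seq_len(n))
  targets <- sprintf("T%03d", seq_len(config$n_targets))
  biomarkers <- sprintf("B%03d", seq_len(config$n_biomarkers))
  cohort_lines <- lines[seq_len(config$n_cohort)]
  other_lines <- setdiff(lines, cohort_lines)

  ann <- data.frame(
    cellline_id = lines,
    tumor_type = c(rep("cohort", config$n_cohort),
                   sample(sprintf("other%02d", 1:8), n - config$n_cohort,
                          replace = TRUE)),
    stringsAsFactors = FALSE)

  freq <- runif(config$n_biomarkers, config$mutation_freq_range[1],
                config$mutation_freq_range[2])
  M <- matrix(rbinom(config$n_biomarkers * n, 1, rep(freq, times = n)),
              nrow = config$n_biomarkers, ncol = n,
              dimnames = list(biomarkers, lines))
  # exact cohort mutant counts for planted pairs that request them
  for (pl in config$planted) {
    if (!is.null(pl$n_mut)) {
      mut <- sample(cohort_lines, pl$n_mut)
      M[pl$biomarker, cohort_lines] <- as.integer(cohort_lines %in% mut)
    }
  }

  E <- matrix(rnorm(config$n_targets * n, mean = config$base_score_mean,
                    sd = config$noise_sd),
              nrow = config$n_targets, ncol = n,
              dimnames = list(targets, lines))
  E <- E + rnorm(config$n_targets, 0, config$target_effect_sd)  # row offsets
  for (bg in config$essential_background) {
    E[bg$target, ] <- E[bg$target, ] + bg$shift
  }
  truth_pairs <- list()
  for (pl in config$planted) {
    cohort_only <- if (is.null(pl$cohort_only)) TRUE else pl$cohort_only
    cols <- if (cohort_only) cohort_lines else lines
    mut_cols <- cols[M[pl$biomarker, cols] == 1]
    E[pl$target, mut_cols] <- E[pl$target, mut_cols] + pl$delta
    wt_cols <- setdiff(cohort_lines, mut_cols)
    truth_pairs[[length(truth_pairs) + 1]] <- list(
      target = pl$target, biomarker = pl$biomarker, delta = pl$delta,
      cohort_only = cohort_only,
      n_mut_cohort = sum(M[pl$biomarker, cohort_lines]),
      realized_delta_ess =
        mean(E[pl$target, intersect(cohort_lines, mut_cols)]) -
        mean(E[pl$target, wt_cols]))
  }

  # expression: high log-normal baseline, with a slice of targets forced low
  planted_targets <- vapply(config$planted, `[[`, "", "target")
  n_low <- round(config$low_expression_fraction * config$n_targets)
  low_candidates <- setdiff(targets, planted_targets)
  low_targets <- if (n_low > 0) sample(low_candidates, min(n_low, length(low_candidates)))
    else character(0)
  meanlog <- ifelse(targets %in% low_targets, log(0.5), log(20))
  X <- matrix(rlnorm(config$n_targets * n, meanlog = rep(meanlog, times = n),
                     sdlog = 1),
              nrow = config$n_targets, ncol = n,
              dimnames = list(targets, lines))

  miss <- matrix(FALSE, config$n_targets, n, dimnames = dimnames(E))
  if (config$missing_rate > 0) {
    miss[] <- runif(length(E)) < config$missing_rate
    # keep every row imputable
    bad <- rowSums(!miss) < 2
    miss[bad, ] <- FALSE
  }
  Ena <- E
  Ena[miss] <- NA_real_

  n_drugs <- sample(0:3, config$n_targets, replace = TRUE)
  dti <- NULL
  if (sum(n_drugs) > 0) {
    dti <- data.frame(
      drug_id = sprintf("D%04d", seq_len(sum(n_drugs))),
      target = rep(targets, n_drugs),
      potency_uM = round(runif(sum(n_drugs), 0.01, 5), 4),
      potency_kind = sample(c("IC50", "Ki", "none"), sum(n_drugs),
                            replace = TRUE, prob = c(0.45, 0.3, 0.25)),
      source = "synthetic",
      stringsAsFactors = FALSE)
    dti$potency_uM[dti$potency_kind == "none"] <- NA_real_
  }

  decoys <- data.frame(
    gene1 = sample(targets, config$n_decoy_interactions, replace = TRUE),
    gene2 = sample(biomarkers, config$n_decoy_interactions, replace = TRUE),
    stringsAsFactors = FALSE)
  planted_int <- if (length(config$planted)) data.frame(
    gene1 = vapply(config$planted, `[[`, "", "target"),
    gene2 = vapply(config$planted, `[[`, "", "biomarker"),
    stringsAsFactors = FALSE) else NULL
  interactions <- unique(rbind(planted_int, decoys))
  rownames(interactions) <- NULL

  bundle <- align_panel(essentiality_matrix(Ena, miss), M, X, ann,
                        dti = dti, interactions = interactions)
  truth <- list(planted = truth_pairs,
                mutation_freq = setNames(freq, biomarkers),
                realized_mutants = rowSums(M),
                low_expression_targets = sort(low_targets),
                config = config)
  list(bundle = bundle,
       cohort = select_cohort(ann, tumor_type = "cohort"),
       truth = truth)
}

#' Write a synthetic bundle to disk in the formats the readers accept
#'
#' Emits `essentiality.tsv` (with NA at masked positions), `mutation.tsv`,
#' `expression.tsv`, `annotation.tsv`, `dti.tsv`, `interactions.tsv` and a
#' MAF-like `variants.maf` derived from the mutation matrix (one
#' Missense_Mutation row per mutant entry).
#'
#' @param bundle a `screen_bundle` (see [generate_bundle()]).
#' @param dir output directory (created if needed).
#' @return named character vector of the written file paths.
#' @export
write_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(essentiality = file.path(dir, "essentiality.tsv"),
             mutation = file.path(dir, "mutation.tsv"),
             expression = file.path(dir, "expression.tsv"),
             annotation = file.path(dir, "annotation.tsv"),
             dti = file.path(dir, "dti.tsv"),
             interactions = file.path(dir, "interactions.tsv"),
             variants = file.path(dir, "variants.maf"))
  write_mat <- function(m, path) {
    df <- data.frame(id = rownames(m),
                     format(m, digits = 15, trim = TRUE, scientific = NA),
                     check.names = FALSE, stringsAsFactors = FALSE)
    df[df == "NA"] <- "NA"
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_mat(bundle$essentiality$values, paths["essentiality"])
  write_int <- function(m, path) {
    df <- data.frame(id = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_int(bundle$mutation, paths["mutation"])
  write_mat(bundle$expression, paths["expression"])
  utils::write.table(bundle$annotation, paths["annotation"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(bundle$dti)) {
    utils::write.table(bundle$dti, paths["dti"], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(bundle$interactions)) {
    utils::write.table(bundle$interactions, paths["interactions"], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  idx <- which(bundle$mutation == 1, arr.ind = TRUE)
  maf <- data.frame(
    Hugo_Symbol = rownames(bundle$mutation)[idx[, 1]],
    Tumor_Sample_Barcode = colnames(bundle$mutation)[idx[, 2]],
    Variant_Classification = "Missense_Mutation",
    stringsAsFactors = FALSE)
  maf <- maf[order(maf$Hugo_Symbol, maf$Tumor_Sample_Barcode), , drop = FALSE]
  utils::write.table(maf, paths["variants"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

#' Read a written bundle back from disk
#'
#' Inverse of [write_bundle()]: reads the matrices and tables and aligns
#' them into a `screen_bundle`.
#'
#' @param dir directory written by [write_bundle()].
#' @return a `screen_bundle`.
#' @export
read_bundle <- function(dir) {
  E <- read_matrix(file.path(dir, "essentiality.tsv"), "essentiality")
  M <- read_matrix(file.path(dir, "mutation.tsv"), "mutation")
  X <- read_matrix(file.path(dir, "expression.tsv"), "expression")
  ann <- read_annotation(file.path(dir, "annotation.tsv"))
  dti_path <- file.path(dir, "dti.tsv")
  int_path <- file.path(dir, "interactions.tsv")
  align_panel(E, M, X, ann,
              dti = if (file.exists(dti_path)) read_dti(dti_path) else NULL,
              interactions = if (file.exists(int_path)) read_interactions(int_path) else NULL)
}
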