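# Readers, validation and alignment for the input tables, MAF dichotomization
# and k-NN imputation of missing essentiality scores.

#' Construct an essentiality matrix
#'
#' Wraps a numeric targets x cell-lines score matrix together with its mask of
#' missing entries. More negative scores mean the knockdown is more lethal.
#'
#' @param values numeric matrix (targets in rows, cell lines in columns) with
#'   rownames and colnames set; `NA` entries are taken as missing.
#' @param missing_mask optional logical matrix of the same shape; defaults to
#'   `is.na(values)`.
#' @return An object of class `ess_matrix`: a list with elements `values`
#'   (numeric matrix) and `missing_mask` (logical matrix).
#' @export
essentiality_matrix <- function(values, missing_mask = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(missing_mask)) missing_mask <- is.na(values)
  stopifnot(identical(dim(values), dim(missing_mask)))
  check_ids(rownames(values), "target")
  check_ids(colnames(values), "cell line")
  if (any(!is.finite(values[!missing_mask]))) {
    stop("essentiality scores must be finite where not missing")
  }
  values[missing_mask] <- NA_real_
  structure(list(values = values, missing_mask = missing_mask),
            class = "ess_matrix")
}

#' @export
print.ess_matrix <- function(x, ...) {
  cat(sprintf("Essentiality matrix: %d targets x %d cell lines (%d missing entries)\n",
              nrow(x$values), ncol(x$values), sum(x$missing_mask)))
  invisible(x)
}

#' @export
dim.ess_matrix <- function(x) dim(x$values)

check_ids <- function(ids, what) {
  if (is.null(ids) || length(ids) == 0) stop("no ", what, " identifiers")
  if (anyNA(ids) || any(!nzchar(ids))) stop("empty ", what, " identifier")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("duplicate ", what, " identifiers: ", paste(dup, collapse = ", "))
  }
  invisible(ids)
}

#' Read an essentiality, mutation or expression matrix from TSV/CSV
#'
#' First column holds row identifiers (gene symbols), the header row holds
#' cell-line identifiers. The delimiter is sniffed unless `sep` is given.
#' Empty cells and "NA" become missing values for essentiality matrices, are
#' an error for mutation matrices, and become 0 (with a warning) for
#' expression matrices.
#'
#' @param path file path.
#' @param kind one of "essentiality", "mutation", "expression".
#' @param sep optional field separator; default auto-detected.
#' @return An [essentiality_matrix()] for `kind = "essentiality"`, otherwise a
#'   numeric matrix with gene rownames and cell-line colnames (binary for
#'   mutations, non-negative TPM for expression).
#' @export
read_matrix <- function(path, kind = c("essentiality", "mutation", "expression"),
                        sep = "auto") {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) stop("empty file: ", path)
  dt <- data.table::fread(path, sep = sep, header = TRUE, data.table = FALSE,
                          na.strings = c("NA", ""), colClasses = list(character = 1),
                          check.names = FALSE)
  if (nrow(dt) == 0 || ncol(dt) < 2) stop("no data rows/columns in ", path)
  ids <- as.character(dt[[1]])
  check_ids(ids, "row")
  check_ids(colnames(dt)[-1], "column")
  values <- as.matrix(dt[, -1, drop = FALSE])
  storage.mode(values) <- "double"
  dimnames(values) <- list(ids, colnames(dt)[-1])

  if (kind == "essentiality") {
    return(essentiality_matrix(values))
  }
  if (kind == "mutation") {
    bad <- which(is.na(values) | !(values %in% c(0, 1)), arr.ind = TRUE)
    if (nrow(bad)) {
      stop("mutation matrix must be strictly {0,1}; offending entries: ",
           paste(sprintf("[%s, %s]", ids[bad[, 1]], colnames(values)[bad[, 2]]),
                 collapse = ", "))
    }
    return(values)
  }
  # expression
  if (anyNA(values)) {
    warning(sum(is.na(values)), " missing expression value(s) set to 0 TPM")
    values[is.na(values)] <- 0
  }
  if (any(values < 0)) stop("expression values must be non-negative")
  values
}

#' Read a cell-line annotation table
#'
#' Two-column TSV/CSV mapping cell-line id to tumor-type label.
#'
#' @param path file path.
#' @return data.frame with columns `cellline_id`, `tumor_type`.
#' @export
read_annotation <- function(path) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE,
                          colClasses = "character")
  if (ncol(dt) < 2) stop("annotation needs two columns (cell line, tumor type)")
  ann <- data.frame(cellline_id = dt[[1]], tumor_type = dt[[2]],
                    stringsAsFactors = FALSE)
  check_ids(ann$cellline_id, "cell line")
  ann
}

#' Read a drug-target interaction table
#'
#' Expects columns `drug_id`, `target` and optionally `potency_uM`,
#' `potency_kind` (IC50, Ki or none) and `source`. Duplicate (drug, target)
#' rows are collapsed, keeping the most potent measurement.
#'
#' @param path file path.
#' @return data.frame with columns drug_id, target, potency_uM, potency_kind,
#'   source.
#' @export
read_dti <- function(path) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE,
                          na.strings = c("NA", ""))
  need <- c("drug_id", "target")
  if (!all(need %in% colnames(dt))) {
    stop("DTI table requires columns: ", paste(need, collapse = ", "))
  }
  dti <- data.frame(
    drug_id = as.character(dt$drug_id),
    target = as.character(dt$target),
    potency_uM = if ("potency_uM" %in% colnames(dt)) as.numeric(dt$potency_uM) else NA_real_,
    potency_kind = if ("potency_kind" %in% colnames(dt)) as.character(dt$potency_kind) else "none",
    source = if ("source" %in% colnames(dt)) as.character(dt$source) else NA_character_,
    stringsAsFactors = FALSE)
  dti$potency_kind[is.na(dti$potency_kind)] <- "none"
  if (any(dti$potency_uM <= 0, na.rm = TRUE)) stop("potency_uM must be positive")
  # deduplicate (drug, target), keep lowest potency (most potent evidence)
  o <- order(dti$drug_id, dti$target, dti$potency_uM, na.last = TRUE)
  dti <- dti[o, , drop = FALSE]
  dti <- dti[!duplicated(dti[, c("drug_id", "target")]), , drop = FALSE]
  rownames(dti) <- NULL
  dti
}

#' Read a gene-gene interaction table (STRING-like pairs)
#'
#' @param path file path to a two-column TSV/CSV of gene symbols.
#' @return data.frame with columns `gene1`, `gene2` (unordered pairs).
#' @export
read_interactions <- function(path) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE,
                          colClasses = "character")
  if (ncol(dt) < 2) stop("interaction table needs two gene columns")
  data.frame(gene1 = dt[[1]], gene2 = dt[[2]], stringsAsFactors = FALSE)
}

#' Read a MAF-like variant table
#'
#' Requires columns `Hugo_Symbol`, `Tumor_Sample_Barcode`,
#' `Variant_Classification`; when `t_alt_count`/`t_ref_count` are present the
#' allele fraction is computed as alt / (alt + ref).
#'
#' @param path file path.
#' @return data.frame of variant records with columns `gene`, `cellline`,
#'   `variant_classification`, `allele_fraction`.
#' @export
read_variants <- function(path) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE,
                          na.strings = c("NA", ""))
  need <- c("Hugo_Symbol", "Tumor_Sample_Barcode", "Variant_Classification")
  if (!all(need %in% colnames(dt))) {
    stop("variant table requires columns: ", paste(need, collapse = ", "))
  }
  af <- rep(NA_real_, nrow(dt))
  if (all(c("t_alt_count", "t_ref_count") %in% colnames(dt))) {
    tot <- dt$t_alt_count + dt$t_ref_count
    af <- ifelse(tot > 0, dt$t_alt_count / tot, NA_real_)
  }
  rec <- data.frame(gene = as.character(dt$Hugo_Symbol),
                    cellline = as.character(dt$Tumor_Sample_Barcode),
                    variant_classification = as.character(dt$Variant_Classification),
                    allele_fraction = af,
                    stringsAsFactors = FALSE)
  if (any(!nzchar(rec$gene)) || any(!nzchar(rec$cellline))) {
    stop("variant records must have non-empty gene and cell line")
  }
  bad_af <- !is.na(rec$allele_fraction) &
    (rec$allele_fraction < 0 | rec$allele_fraction > 1)
  if (any(bad_af)) stop("allele fractions must lie in [0, 1]")
  rec
}

#' Default variant classes excluded from dichotomization
#'
#' Non-coding and silent classes, mirroring the convention of keeping only
#' protein-altering variants in the coding sequence.
#' @export
default_excluded_classes <- function() {
  c("Silent", "Intron", "3'UTR", "5'UTR", "5'Flank", "IGR", "RNA")
}

#' Dichotomize variant records into a binary mutation matrix
#'
#' A gene/cell-line entry is 1 iff at least one record for that gene in that
#' line survives the class and allele-fraction filters; absence of any
#' surviving record means wild-type (0). Genes whose records are all filtered
#' out are retained as all-zero rows. Records referencing cell lines outside
#' `celllines` are skipped with a message.
#'
#' @param records data.frame of variant records (see [read_variants()]).
#' @param celllines character vector of panel cell-line ids (matrix columns).
#' @param excluded_classes variant classes to drop;
#'   default [default_excluded_classes()].
#' @param min_allele_fraction drop records with allele fraction strictly below
#'   this value (records without an allele fraction are kept); `NULL` disables.
#' @return binary numeric matrix, genes x cell lines.
#' @export
dichotomize_mutations <- function(records, celllines,
                                  excluded_classes = default_excluded_classes(),
                                  min_allele_fraction = NULL) {
  if (length(celllines) == 0) stop("celllines must be non-empty")
  check_ids(celllines, "cell line")
  genes <- sort(unique(records$gene))
  M <- matrix(0, nrow = length(genes), ncol = length(celllines),
              dimnames = list(genes, celllines))
  unknown <- setdiff(unique(records$cellline), celllines)
  if (length(unknown)) {
    message("skipping variant records for ", length(unknown),
            " cell line(s) not in the panel: ",
            paste(head(unknown, 5), collapse = ", "))
  }
  keep <- records$cellline %in% celllines &
    !(records$variant_classification %in% excluded_classes)
  if (!is.null(min_allele_fraction)) {
    keep <- keep & (is.na(records$allele_fraction) |
                      records$allele_fraction >= min_allele_fraction)
  }
  surv <- records[keep, , drop = FALSE]
  if (nrow(surv)) M[cbind(surv$gene, surv$cellline)] <- 1
  M
}

#' Restrict all inputs to the shared cell-line set
#'
#' Cell lines are intersected across the essentiality, mutation and
#' expression matrices and the annotation; all are reordered to one canonical
#' order (the essentiality matrix's column order restricted to the
#' intersection). A bundle records which lines each source lost.
#'
#' @param E an [essentiality_matrix()].
#' @param M binary mutation matrix (genes x cell lines).
#' @param X expression matrix (genes x cell lines, TPM).
#' @param ann annotation data.frame (`cellline_id`, `tumor_type`).
#' @param dti optional drug-target table (see [read_dti()]).
#' @param interactions optional gene-pair data.frame (`gene1`, `gene2`).
#' @return A `screen_bundle`: list with `essentiality`, `mutation`,
#'   `expression`, `annotation`, `dti`, `interactions`, `dropped`.
#' @export
align_panel <- function(E, M, X, ann, dti = NULL, interactions = NULL) {
  stopifnot(inherits(E, "ess_matrix"))
  common <- intersect(colnames(E$values), colnames(M))
  common <- intersect(common, colnames(X))
  common <- intersect(common, ann$cellline_id)
  if (length(common) < 3) {
    stop("only ", length(common),
         " cell line(s) shared across inputs; need at least 3")
  }
  # canonical order: essentiality column order restricted to the intersection
  common <- colnames(E$values)[colnames(E$values) %in% common]
  dropped <- list(
    essentiality = setdiff(colnames(E$values), common),
    mutation = setdiff(colnames(M), common),
    expression = setdiff(colnames(X), common),
    annotation = setdiff(ann$cellline_id, common))
  Ea <- essentiality_matrix(E$values[, common, drop = FALSE],
                            E$missing_mask[, common, drop = FALSE])
  ann <- ann[match(common, ann$cellline_id), , drop = FALSE]
  rownames(ann) <- NULL
  structure(list(
    essentiality = Ea,
    mutation = M[, common, drop = FALSE],
    expression = X[, common, drop = FALSE],
    annotation = ann,
    dti = dti,
    interactions = interactions,
    dropped = dropped), class = "screen_bundle")
}

#' @export
print.screen_bundle <- function(x, ...) {
  cat(sprintf(
    "Screen bundle: %d cell lines | %d targets | %d mutation genes | %d expression genes\n",
    ncol(x$essentiality$values), nrow(x$essentiality$values),
    nrow(x$mutation), nrow(x$expression)))
  if (!is.null(x$dti)) cat(sprintf("  DTI rows: %d\n", nrow(x$dti)))
  invisible(x)
}

# scaled Euclidean distance of row i to every row, over mutually observed
# coordinates, normalized by the number of shared coordinates
row_distances <- function(values, observed, i) {
  vi <- values[i, ]
  oi <- observed[i, ]
  shared <- observed & rep(oi, each = nrow(values))
  diffs <- sweep(values, 2, vi, "-")
  diffs[!shared] <- 0
  nshared <- rowSums(shared)
  d <- sqrt(rowSums(diffs^2, na.rm = TRUE) / pmax(nshared, 1))
  d[nshared == 0] <- Inf
  d[i] <- Inf
  d
}

#' Impute missing essentiality scores by nearest-neighbour averaging
#'
#' Each missing entry is replaced by the mean, over the `k` nearest target
#' rows that have an observed value in that cell line, of those rows' values.
#' Row-row distance is the Euclidean distance over mutually observed
#' coordinates divided by the square root of their count; ties are broken by
#' row order. Observed entries are never altered.
#'
#' @param E an [essentiality_matrix()].
#' @param k number of neighbour rows (default 10).
#' @return An [essentiality_matrix()] with no missing entries.
#' @export
impute_knn <- function(E, k = 10) {
  stopifnot(inherits(E, "ess_matrix"))
  V <- E$values
  miss <- E$missing_mask
  if (k < 1) stop("k must be at least 1")
  if (k >= nrow(V)) stop("k (", k, ") must be smaller than the number of target rows (",
                         nrow(V), ")")
  if (!any(miss)) return(essentiality_matrix(V, miss))
  obs <- !miss
  nobs <- rowSums(obs)
  if (any(nobs == 0)) {
    stop("target row(s) entirely missing: ",
         paste(rownames(V)[nobs == 0], collapse = ", "))
  }
  if (any(nobs < 2)) {
    stop("every target row needs at least 2 observed values; offending: ",
         paste(rownames(V)[nobs < 2], collapse = ", "))
  }
  Vfill <- V
  for (i in which(rowSums(miss) > 0)) {
    d <- row_distances(V, obs, i)
    for (j in which(miss[i, ])) {
      donors <- which(obs[, j] & is.finite(d))
      if (length(donors) == 0) { # no row observed at j shares coordinates with i
        Vfill[i, j] <- mean(V[i, obs[i, ]])
        next
      }
      ord <- donors[order(d[donors], donors)]
      use <- ord[seq_len(min(k, length(ord)))]
      Vfill[i, j] <- mean(V[use, j])
    }
  }
  essentiality_matrix(Vfill, matrix(FALSE, nrow(V), ncol(V),
                                    dimnames = dimnames(V)))
}

#' Filter a drug-target table by potency
#'
#' Measured rows (IC50 or Ki) are kept iff potency is strictly below the
#' threshold; curated mechanism-of-action rows without a measurement
#' (`potency_kind = "none"`) are always kept.
#'
#' @param dti data.frame as returned by [read_dti()].
#' @param threshold_uM positive potency threshold in micromolar (default 1).
#' @return the filtered data.frame.
#' @export
filter_dti_potency <- function(dti, threshold_uM = 1) {
  if (!is.numeric(threshold_uM) || threshold_uM <= 0) {
    stop("threshold_uM must be positive")
  }
  measured <- dti$potency_kind %in% c("IC50", "Ki")
  keep <- !measured | (!is.na(dti$potency_uM) & dti$potency_uM < threshold_uM)
  out <- dti[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
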