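# Shared fixtures and independent brute-force oracles used across test files.
# Oracles are deliberately naive (per-element loops) so they stay independent
# of the vectorized implementations they check.

rand_ess <- function(nr, nc, seed = 1, row_sd = 0, missing = 0) {
  set.seed(seed)
  V <- matrix(rnorm(nr * nc), nr, nc,
              dimnames = list(sprintf("T%03d", seq_len(nr)),
                              sprintf("L%04d", seq_len(nc))))
  V <- V + rnorm(nr, 0, row_sd)
  mask <- matrix(runif(nr * nc) < missing, nr, nc, dimnames = dimnames(V))
  bad <- rowSums(!mask) < 2
  mask[bad, ] <- FALSE
  V[mask] <- NA
  essentiality_matrix(V, mask)
}

# brute-force k-NN imputation oracle mirroring the documented rule:
# scaled Euclidean distance over mutually observed coordinates, donors must
# be observed at the missing column, ties by row order
oracle_impute <- function(E, k) {
  V <- E$values
  miss <- E$missing_mask
  out <- V
  for (i in seq_len(nrow(V))) for (j in seq_len(ncol(V))) {
    if (!miss[i, j]) next
    d <- rep(Inf, nrow(V))
    for (l in seq_len(nrow(V))) {
      if (l == i) next
      shared <- !miss[i, ] & !miss[l, ]
      if (!any(shared)) next
      d[l] <- sqrt(sum((V[i, shared] - V[l, shared])^2) / sum(shared))
    }
    donors <- which(!miss[, j] & is.finite(d))
    if (!length(donors)) { out[i, j] <- mean(V[i, !miss[i, ]]); next }
    ord <- donors[order(d[donors], donors)]
    out[i, j] <- mean(V[ord[seq_len(min(k, length(ord)))], j])
  }
  out
}

# write a small matrix in the on-disk dialect the readers expect
write_small_matrix <- function(m, path, sep = "\t") {
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  path
}

tiny_annotation <- function(lines, cohort_lines) {
  data.frame(cellline_id = lines,
             tumor_type = ifelse(lines %in% cohort_lines, "cohort", "other"),
             stringsAsFactors = FALSE)
}

planted_config <- function(seed, delta = -3.9, n_mut = 6, ...) {
  synthetic_config(
    planted = list(list(target = "T001", biomarker = "B001",
                        delta = delta, cohort_only = TRUE, n_mut = n_mut)),
    seed = seed, ...)
}
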