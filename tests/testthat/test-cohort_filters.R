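# Cohort selection and the three target pre-filters.

test_that("select_cohort selects by tumor type or explicit ids", {
  lines <- sprintf("L%03d", 1:30)
  ann <- tiny_annotation(lines, lines[1:5])
  co <- select_cohort(ann, tumor_type = "cohort")
  expect_s3_class(co, "cohort")
  expect_identical(co$member_ids, lines[1:5])
  expect_identical(co$complement_ids, lines[6:30])
  expect_length(intersect(co$member_ids, co$complement_ids), 0)

  co2 <- select_cohort(ann, id_list = c("L010", "L002", "L020", "L001"))
  expect_identical(co2$member_ids, c("L010", "L002", "L020", "L001"))

  expect_error(select_cohort(ann, tumor_type = "XYZ"), "XYZ")
  expect_error(select_cohort(ann, id_list = c("L001", "nope")), "nope")
})

test_that("essential_fraction counts strictly below the cutoff", {
  expect_equal(essential_fraction(c(-3, -1, -2.5, 0), cutoff = -2), 0.5)
  expect_equal(essential_fraction(c(-2, -2), cutoff = -2), 0)  # strict
  set.seed(5)
  x <- rnorm(1000, sd = 2)
  expect_equal(essential_fraction(x, -2), sum(x < -2) / 1000)
  expect_error(essential_fraction(numeric(0)), "empty")
  expect_error(essential_fraction(c(1, NA)), "missing")
})

test_that("specificity_stats builds the 2x2 table with Haldane correction only when needed", {
  mk_scores <- function(a, b, c, d, cutoff = -2) {
    mem <- sprintf("m%02d", seq_len(a + b))
    oth <- sprintf("o%02d", seq_len(c + d))
    sc <- setNames(c(rep(cutoff - 1, a), rep(cutoff + 1, b),
                     rep(cutoff - 1, c), rep(cutoff + 1, d)), c(mem, oth))
    co <- structure(list(name = "x", member_ids = mem, complement_ids = oth),
                    class = "cohort")
    list(scores = sc, cohort = co)
  }
  f <- mk_scores(3, 2, 2, 18)
  st <- specificity_stats(f$scores, f$cohort)
  expect_equal(st$odds_ratio, 13.5)
  expect_equal(st$other_fraction, 0.1)

  f0 <- mk_scores(0, 5, 0, 20)
  st0 <- specificity_stats(f0$scores, f0$cohort)
  expect_equal(st0$odds_ratio, (0.5 * 20.5) / (5.5 * 0.5), tolerance = 1e-12)
  expect_equal(st0$other_fraction, 0)

  # identical essential fractions give OR = 1 without correction
  fe <- mk_scores(2, 8, 4, 16)
  expect_equal(specificity_stats(fe$scores, fe$cohort)$odds_ratio, 1)

  # swapping cohort and complement inverts the OR
  sw <- structure(list(name = "x", member_ids = f$cohort$complement_ids,
                       complement_ids = f$cohort$member_ids), class = "cohort")
  expect_equal(specificity_stats(f$scores, sw)$odds_ratio, 1 / st$odds_ratio)
})

test_that("expressed_fraction uses an inclusive TPM floor", {
  expect_equal(expressed_fraction(c(0.5, 1.0, 2.0, 3.0), 1), 0.75)
  expect_equal(expressed_fraction(rep(0, 5), 1), 0)
  set.seed(6)
  x <- rlnorm(200)
  expect_equal(expressed_fraction(x, 1), sum(x >= 1) / 200)
  expect_error(expressed_fraction(numeric(0)), "empty")
})

test_that("target_prefilter agrees with a brute-force per-predicate oracle", {
  set.seed(77)
  n_t <- 200; n_mem <- 22; n_oth <- 60
  lines <- sprintf("L%03d", seq_len(n_mem + n_oth))
  mem <- lines[seq_len(n_mem)]
  # heterogeneous targets: some essential in the cohort, some everywhere
  V <- matrix(rnorm(n_t * length(lines)), n_t,
              dimnames = list(sprintf("T%03d", 1:n_t), lines))
  shift_coh <- sample(c(0, -2, -3), n_t, TRUE, prob = c(0.5, 0.3, 0.2))
  shift_all <- sample(c(0, -2.5), n_t, TRUE, prob = c(0.8, 0.2))
  V[, mem] <- V[, mem] + shift_coh
  V <- V + shift_all
  X <- matrix(rlnorm(n_t * length(lines),
                     meanlog = sample(c(log(0.3), log(10)), n_t, TRUE)),
              n_t, dimnames = dimnames(V))
  E <- essentiality_matrix(V)
  co <- select_cohort(tiny_annotation(lines, mem), tumor_type = "cohort")
  par <- filter_params()
  rep_ <- target_prefilter(E, X, co, par)

  for (i in seq_len(n_t)) {
    sc <- V[i, ]
    coh_f <- mean(sc[mem] < -2)
    oth_f <- mean(sc[setdiff(lines, mem)] < -2)
    a <- sum(sc[mem] < -2); b <- n_mem - a
    cc <- sum(sc[setdiff(lines, mem)] < -2); d <- n_oth - cc
    or <- if (min(a, b, cc, d) == 0) {
      ((a + .5) * (d + .5)) / ((b + .5) * (cc + .5))
    } else (a * d) / (b * cc)
    ex_f <- mean(X[i, mem] >= 1)
    pass <- (coh_f > 0.2) && (or > 1) && (oth_f <= 0.2) && (ex_f > 0.75)
    expect_equal(rep_$cohort_essential_fraction[i], coh_f)
    expect_equal(rep_$odds_ratio[i], or)
    expect_identical(rep_$pass[i], pass)
  }
  expect_identical(rep_$pass,
                   rep_$pass_essential & rep_$pass_specific & rep_$pass_expressed)
  # some variety so the oracle check is informative
  expect_gt(sum(rep_$pass), 0)
  expect_lt(sum(rep_$pass), n_t)

  # single-predicate veto: cohort fraction at 4/22 fails regardless
  V2 <- V
  V2[1, ] <- 0
  V2[1, mem[1:4]] <- -3
  rep2 <- target_prefilter(essentiality_matrix(V2), X, co, par)
  expect_false(rep2$pass[1])
  expect_false(rep2$pass_essential[1])

  # targets absent from the expression matrix fail the expression criterion
  expect_message(
    rep3 <- target_prefilter(E, X[-1, , drop = FALSE], co, par),
    "absent")
  expect_false(rep3$pass_expressed[1])
  expect_equal(rep3$expressed_fraction[1], 0)
})

test_that("pass sets shrink monotonically as thresholds tighten", {
  set.seed(42)
  gen <- generate_bundle(synthetic_config(n_panel = 80, n_cohort = 15,
                                          n_targets = 100, n_biomarkers = 5,
                                          target_effect_sd = 1, seed = 42))
  E <- gen$bundle$essentiality; X <- gen$bundle$expression
  co <- gen$cohort
  base <- target_prefilter(E, X, co, filter_params())
  # lowering the cutoff (more negative) never increases essential fractions
  lower <- target_prefilter(E, X, co, filter_params(essentiality_cutoff = -2.5))
  expect_true(all(lower$cohort_essential_fraction <= base$cohort_essential_fraction))
  # raising min_tpm never increases expressed fractions
  tpm2 <- target_prefilter(E, X, co, filter_params(min_tpm = 2))
  expect_true(all(tpm2$expressed_fraction <= base$expressed_fraction))
  # tightening any threshold shrinks the pass set
  tight <- target_prefilter(E, X, co,
                            filter_params(min_cohort_essential_fraction = 0.4,
                                          max_other_essential_fraction = 0.1,
                                          min_expressed_fraction = 0.9))
  expect_true(all(tight$pass <= base$pass))
})
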