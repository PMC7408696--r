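# Screen orchestration: drug mapping, interaction evidence, co-occurrence,
# query consistency, determinism, and the case-by-case pair test.

test_that("map_targets_to_drugs matches a brute-force scan", {
  dti <- data.frame(drug_id = c("volasertib", "BI2536", "drugX"),
                    target = c("PLK1", "PLK1", "AURKA"),
                    potency_uM = NA, potency_kind = "none", source = "s",
                    stringsAsFactors = FALSE)
  mp <- map_targets_to_drugs(c("PLK1", "TP53"), dti)
  expect_identical(mp$PLK1, c("BI2536", "volasertib"))  # deterministic order
  expect_identical(mp$TP53, character(0))

  set.seed(51)
  rnd <- data.frame(drug_id = sample(sprintf("D%02d", 1:30), 120, TRUE),
                    target = sample(LETTERS[1:10], 120, TRUE),
                    stringsAsFactors = FALSE)
  mp2 <- map_targets_to_drugs(LETTERS[1:10], rnd)
  for (tg in LETTERS[1:10]) {
    oracle <- character(0)
    for (i in seq_len(nrow(rnd))) {
      if (rnd$target[i] == tg && !rnd$drug_id[i] %in% oracle) {
        oracle <- c(oracle, rnd$drug_id[i])
      }
    }
    expect_setequal(mp2[[tg]], oracle)
  }
})

test_that("interaction_filter flags and filters by unordered membership", {
  pairs <- data.frame(target = c("PLK1", "AURKA"),
                      biomarker = c("CREBBP", "TP53"),
                      stringsAsFactors = FALSE)
  ints <- data.frame(gene1 = "CREBBP", gene2 = "PLK1")  # reversed order
  out <- interaction_filter(pairs, ints)
  expect_identical(out$interaction_supported, c(TRUE, FALSE))
  out2 <- interaction_filter(pairs, ints, require_interaction = TRUE)
  expect_equal(nrow(out2), 1)
  expect_equal(out2$target, "PLK1")
  # empty interaction set with the requirement on empties the output
  out3 <- interaction_filter(pairs, NULL, require_interaction = TRUE)
  expect_equal(nrow(out3), 0)

  set.seed(52)
  rp <- data.frame(target = sample(LETTERS[1:8], 50, TRUE),
                   biomarker = sample(letters[1:8], 50, TRUE),
                   stringsAsFactors = FALSE)
  ri <- data.frame(gene1 = sample(c(LETTERS[1:8], letters[1:8]), 20, TRUE),
                   gene2 = sample(c(LETTERS[1:8], letters[1:8]), 20, TRUE),
                   stringsAsFactors = FALSE)
  got <- interaction_filter(rp, ri)$interaction_supported
  for (i in seq_len(nrow(rp))) {
    hit <- FALSE
    for (j in seq_len(nrow(ri))) {
      if (setequal(c(rp$target[i], rp$biomarker[i]), c(ri$gene1[j], ri$gene2[j]))) hit <- TRUE
    }
    expect_identical(got[i], hit)
  }
})

test_that("mutation_cooccurrence reproduces the exact hypergeometric p", {
  lines <- sprintf("L%02d", 1:10)
  M <- rbind(g1 = rep(c(1, 0), each = 5), g2 = rep(c(1, 0), each = 5),
             g3 = c(1, 0, 1, 0, 1, 0, 1, 0, 1, 0))
  colnames(M) <- lines
  res <- mutation_cooccurrence(M, "g1")
  expect_false("g1" %in% res$gene)  # self excluded
  # perfectly co-occurring pair: both margins 5/10, p = 2 / choose(10,5)
  expect_equal(res$p_value[res$gene == "g2"], 2 / choose(10, 5),
               tolerance = 1e-12)
  expect_equal(res$p_value[res$gene == "g2"], 1 / 126, tolerance = 1e-10)
  expect_true(all(diff(res$p_value) >= 0))  # sorted ascending

  # independent random mutations yield no Bonferroni-significant hits in
  # most seeds
  hits <- 0
  for (s in 1:10) {
    set.seed(s)
    Mr <- matrix(rbinom(20 * 30, 1, 0.3), 20, 30,
                 dimnames = list(sprintf("g%02d", 1:20), sprintf("L%02d", 1:30)))
    r <- mutation_cooccurrence(Mr, "g01")
    if (any(r$p_value < 0.05 / nrow(r))) hits <- hits + 1
  }
  expect_lte(hits, 1)

  expect_error(mutation_cooccurrence(M, "nope"), "nope")
  expect_error(mutation_cooccurrence(M[, 1:3], "g1"), "4 lines")
})

test_that("screen recovers a planted pair at rank 1 with the right direction", {
  gen <- generate_bundle(planted_config(seed = 1001))
  res <- run_screen(gen$bundle, gen$cohort)
  expect_s3_class(res, "ranked_pairs")
  expect_gt(nrow(res), 0)
  expect_equal(res$target[1], "T001")
  expect_equal(res$biomarker[1], "B001")
  expect_equal(res$direction[1], "mutant-sensitive")
  expect_lt(res$delta_ess[1], 0)
  expect_equal(res$n_mut[1], 6)
  # planted pair is in the interaction set by construction
  expect_true(res$interaction_supported[1])
  man <- attr(res, "manifest")
  expect_equal(man$n_reported_pairs, nrow(res))
  expect_gte(man$n_tested_pairs, man$n_reported_pairs)
})

test_that("query restriction returns exactly the matching mode-all rows", {
  gen <- generate_bundle(planted_config(seed = 1002))
  all_res <- run_screen(gen$bundle, gen$cohort)
  df_all <- as.data.frame(all_res)

  by_target <- run_screen(gen$bundle, gen$cohort, mode = "targets",
                          items = "T001")
  expect_equal(as.data.frame(by_target),
               df_all[df_all$target == "T001", ],
               ignore_attr = TRUE)

  by_mut <- run_screen(gen$bundle, gen$cohort, mode = "mutations",
                       items = c("B001", "B002"))
  expect_equal(as.data.frame(by_mut),
               df_all[df_all$biomarker %in% c("B001", "B002"), ],
               ignore_attr = TRUE)

  drugs_of_t001 <- gen$bundle$dti$drug_id[gen$bundle$dti$target == "T001"]
  if (length(drugs_of_t001)) {
    by_drug <- run_screen(gen$bundle, gen$cohort, mode = "drugs",
                          items = drugs_of_t001[1])
    qt <- unique(gen$bundle$dti$target[gen$bundle$dti$drug_id == drugs_of_t001[1]])
    expect_equal(as.data.frame(by_drug), df_all[df_all$target %in% qt, ],
                 ignore_attr = TRUE)
  }

  # unknown query items produce a naming error
  expect_error(run_screen(gen$bundle, gen$cohort, mode = "targets",
                          items = c("T001", "NOPE")), "NOPE")
  expect_error(run_screen(gen$bundle, gen$cohort, mode = "mutations",
                          items = "ZZZ"), "ZZZ")
  expect_error(run_screen(gen$bundle, gen$cohort, mode = "all",
                          items = "T001"), "items")
})

test_that("thresholds are monotone and ranking is totally ordered", {
  gen <- generate_bundle(planted_config(seed = 1003))
  base <- run_screen(gen$bundle, gen$cohort)
  tight1 <- run_screen(gen$bundle, gen$cohort,
                       params = screen_params(max_lfdr = 0.1))
  tight2 <- run_screen(gen$bundle, gen$cohort,
                       params = screen_params(min_abs_delta_ess = 3))
  key <- function(x) paste(x$target, x$biomarker)
  expect_true(all(key(tight1) %in% key(base)))
  expect_true(all(key(tight2) %in% key(base)))
  # ranking keys are non-decreasing in the tie-break chain
  if (nrow(base) > 1) {
    expect_true(all(diff(base$lfdr) >= 0))
  }
})

test_that("identical inputs give byte-identical ranked TSV output", {
  dir1 <- withr::local_tempdir()
  gen1 <- generate_bundle(planted_config(seed = 1004))
  res1 <- run_screen(gen1$bundle, gen1$cohort)
  write_ranked_pairs(res1, file.path(dir1, "a.tsv"), seed = 7)
  gen2 <- generate_bundle(planted_config(seed = 1004))
  res2 <- run_screen(gen2$bundle, gen2$cohort)
  write_ranked_pairs(res2, file.path(dir1, "b.tsv"), seed = 7)
  expect_identical(readLines(file.path(dir1, "a.tsv")),
                   readLines(file.path(dir1, "b.tsv")))
})

test_that("test_pair agrees with the screen row and works without the prefilter", {
  gen <- generate_bundle(planted_config(seed = 1005))
  res <- run_screen(gen$bundle, gen$cohort)
  tp <- test_pair(gen$bundle, gen$cohort, "T001", "B001")
  expect_true(tp$in_screen_model)
  row <- res[res$target == "T001" & res$biomarker == "B001", ]
  expect_equal(tp$p_value, row$p_value, tolerance = 1e-12)
  expect_equal(tp$lfdr, row$lfdr, tolerance = 1e-12)
  expect_equal(tp$delta_ess, row$delta_ess, tolerance = 1e-12)
  expect_lt(tp$p_value, 0.01)
  expect_lt(tp$delta_ess, 0)

  # a target that fails the prefilter can still be assessed case by case
  rep_ <- attr(res, "report")
  failed <- rep_$target[!rep_$pass][1]
  tp2 <- test_pair(gen$bundle, gen$cohort, failed, "B001")
  expect_false(tp2$in_screen_model)
  expect_true(tp2$lfdr >= 0 && tp2$lfdr <= 1)
  expect_true(tp2$p_value >= 0 && tp2$p_value <= 1)

  # biomarker with no cohort mutants is refused with the group-size reason
  M <- gen$bundle$mutation
  M <- rbind(M, BZZZ = 0)
  gen$bundle$mutation <- M
  expect_error(test_pair(gen$bundle, gen$cohort, "T001", "BZZZ"),
               "group too small")
})

test_that("a global-null bundle usually yields an empty ranked list", {
  empty_count <- 0
  n_seeds <- 5
  for (s in seq_len(n_seeds)) {
    gen <- generate_bundle(synthetic_config(n_panel = 120, n_cohort = 22,
                                            n_targets = 150, n_biomarkers = 15,
                                            seed = 3000 + s))
    res <- suppressWarnings(run_screen(gen$bundle, gen$cohort))
    if (nrow(res) == 0) empty_count <- empty_count + 1
  }
  expect_gte(empty_count, n_seeds - 1)
})
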