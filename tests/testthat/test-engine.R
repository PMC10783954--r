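# Small planted dataset shared across engine tests.
engine_dataset <- function(n = 240, n_decoys = 3, effect = 3, seed = 101) {
  generate(synth_spec(n_samples = n, n_groups = 4, effect_size = effect,
                      n_signal_genes = 15, n_noise_genes = 60,
                      n_decoy_pathways = n_decoys, seed = seed))
}

fast_config <- function(...) {
  run_config(k = 15, n_permutations = 49, seed = 7, ...)
}

test_that("z-score normalization uses the population SD and handles degeneracy", {
  m <- matrix(c(1, 2, 3), 3, 1, dimnames = list(paste0("s", 1:3), "g1"))
  z <- normalize_genes(m, "zscore")
  expect_equal(round(as.numeric(z), 4), c(-1.2247, 0, 1.2247))
  m2 <- cbind(m, g2 = c(5, 5, 5))
  expect_warning(z2 <- normalize_genes(m2, "zscore"), "zero-variance")
  expect_equal(as.numeric(z2[, "g2"]), c(0, 0, 0))
  expect_identical(normalize_genes(m2, "none"), m2)
})

test_that("pathways without enough matched genes are skipped with a reason", {
  ds <- engine_dataset()
  res <- score_pathway(ds$expr, c("absent1", "absent2"), ds$pheno$phenotype,
                       fast_config())
  expect_identical(res$status, "skipped")
  expect_equal(res$n_genes_used, 0L)
  expect_match(res$reason, "0 of 2")
})

test_that("a planted pathway scores near 1 with the floor p-value", {
  ds <- engine_dataset()
  res <- score_pathway(ds$expr, ds$pathways$signal, ds$pheno$phenotype,
                       fast_config())
  expect_identical(res$status, "ok")
  expect_gte(res$score$ami, 0.9)
  expect_equal(res$p_value, 1 / 50)
  expect_equal(res$n_genes_used, 15L)
})

test_that("pure-noise pathways score near zero across seeds", {
  amis <- vapply(1:20, function(seed) {
    ds <- engine_dataset(n = 300, n_decoys = 1, seed = seed)
    cfg <- run_config(k = 15, n_permutations = 0, seed = seed)
    score_pathway(ds$expr, ds$pathways$decoy_001, ds$pheno$phenotype,
                  cfg)$score$ami
  }, numeric(1))
  expect_true(all(abs(amis) <= 0.05))
})

test_that("score_all ranks the signal first and annotates q-values", {
  ds <- engine_dataset()
  tab <- score_all(ds$expr, ds$pathways, ds$pheno, "phenotype", fast_config())
  expect_s3_class(tab, "data.frame")
  expect_identical(tab$pathway[tab$rank == 1], "signal")
  expect_true(all(tab$status == "ok"))
  expect_true(all(tab$q_value >= 0 & tab$q_value <= 1))
  expect_setequal(tab$rank, 1:4)
})

test_that("single pathway gets rank 1 and empty collections error", {
  ds <- engine_dataset(n_decoys = 0)
  tab <- score_all(ds$expr, ds$pathways["signal"], ds$pheno, "phenotype",
                   fast_config())
  expect_equal(tab$rank, 1)
  expect_error(score_all(ds$expr, list(), ds$pheno, "phenotype", fast_config()),
               "empty pathway collection")
})

test_that("identical AMI scores share a tied-average rank", {
  ds <- engine_dataset()
  pathways <- list(signal = ds$pathways$signal,
                   signal_copy = ds$pathways$signal,
                   decoy = ds$pathways$decoy_001)
  cfg <- run_config(k = 15, n_permutations = 0, seed = 7)
  tab <- score_all(ds$expr, pathways, ds$pheno, "phenotype", cfg)
  # both planted copies reach AMI exactly 1 and split ranks 1 and 2
  expect_equal(tab$ami[tab$pathway %in% c("signal", "signal_copy")], c(1, 1))
  expect_equal(tab$rank[tab$pathway %in% c("signal", "signal_copy")],
               c(1.5, 1.5))
  expect_equal(tab$rank[tab$pathway == "decoy"], 3)
})

test_that("results are independent of pathway order and fully deterministic", {
  ds <- engine_dataset()
  cfg <- fast_config()
  tab1 <- score_all(ds$expr, ds$pathways, ds$pheno, "phenotype", cfg)
  tab2 <- score_all(ds$expr, rev(ds$pathways), ds$pheno, "phenotype", cfg)
  reordered <- tab2[match(tab1$pathway, tab2$pathway), ]
  rownames(reordered) <- NULL
  expect_equal(tab1, reordered)
  tab3 <- score_all(ds$expr, ds$pathways, ds$pheno, "phenotype", cfg)
  expect_identical(tab1, tab3)
})

test_that("skipped pathways are reported, not silently dropped", {
  ds <- engine_dataset()
  pathways <- c(ds$pathways, list(tiny = c("SIG001", "SIG002")))
  tab <- score_all(ds$expr, pathways, ds$pheno, "phenotype", fast_config())
  expect_identical(tab$status[tab$pathway == "tiny"], "skipped")
  expect_true(is.na(tab$rank[tab$pathway == "tiny"]))
  expect_false(any(is.na(tab$rank[tab$status == "ok"])))
})

test_that("misaligned inputs are rejected", {
  ds <- engine_dataset()
  pheno_bad <- ds$pheno[rev(seq_len(nrow(ds$pheno))), ]
  expect_error(score_all(ds$expr, ds$pathways, pheno_bad, "phenotype",
                         fast_config()), "not aligned")
  expect_error(score_all(ds$expr, ds$pathways, ds$pheno, "missing_col",
                         fast_config()), "missing_col")
})

test_that("conditioning on an unrelated confounder leaves scores unchanged", {
  sp <- synth_spec(n_samples = 300, n_groups = 4, effect_size = 3,
                   n_signal_genes = 15, n_noise_genes = 60,
                   n_decoy_pathways = 0, confounder_groups = 2, seed = 55)
  ds <- generate(sp)
  cfg <- run_config(k = 15, n_permutations = 0, seed = 7)
  plain <- score_pathway(ds$expr, ds$pathways$signal, ds$pheno$phenotype, cfg)
  cond <- score_pathway(ds$expr, ds$pathways$signal, ds$pheno$phenotype, cfg,
                        confounder = ds$pheno$confounder)
  expect_lt(abs(plain$score$ami - cond$score$ami), 0.02)
})

test_that("subsample reproducibility returns the expected shapes and bounds", {
  ds <- engine_dataset(n = 300)
  cfg <- run_config(k = 10, n_permutations = 0, seed = 3)
  rep2 <- subsample_reproducibility(ds$expr, ds$pathways, ds$pheno,
                                    "phenotype", cfg, fraction = 0.5,
                                    n_repeats = 2)
  expect_equal(dim(rep2$correlations), c(2L, 2L))
  expect_equal(rep2$mean_correlation, rep2$correlations[1, 2])
  expect_error(
    subsample_reproducibility(ds$expr, ds$pathways, ds$pheno, "phenotype",
                              cfg, fraction = 0.02, n_repeats = 2),
    "too small"
  )
})

test_that("full-fraction repeats differ only by optimizer stochasticity", {
  ds <- engine_dataset(n = 200, n_decoys = 5)
  cfg <- run_config(k = 10, n_permutations = 0, seed = 3)
  res <- subsample_reproducibility(ds$expr, ds$pathways, ds$pheno,
                                   "phenotype", cfg, fraction = 1,
                                   n_repeats = 3)
  expect_gte(res$mean_correlation, 0.99)
})

test_that("score tables round-trip through TSV", {
  ds <- engine_dataset()
  cfg <- run_config(k = 15, n_permutations = 0, seed = 7)
  tab <- score_all(ds$expr, ds$pathways, ds$pheno, "phenotype", cfg)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_score_table(tab, f)
  back <- read.delim(f)
  expect_identical(back$pathway, tab$pathway)
  expect_equal(back$ami, tab$ami, tolerance = 1e-12)
})
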