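# The synthetic-data generator: determinism, permutation invariants,
# planted-signal behaviour.

test_that("seed fan-out is stable and component-local", {
  expect_identical(fan_seed(1, "a"), fan_seed(1, "a"))
  expect_false(fan_seed(1, "a") == fan_seed(1, "b"))
  expect_false(fan_seed(1, "a") == fan_seed(2, "a"))
  expect_true(fan_seed(123456, "profile/x") < 2^31)
})

test_that("time-course DE tables are deterministic and recoverable", {
  de1 <- simulate_timecourse_de(n_genes = 400, n_timepoints = 2,
                                n_signature_genes = 30, seed = 5)
  de2 <- simulate_timecourse_de(n_genes = 400, n_timepoints = 2,
                                n_signature_genes = 30, seed = 5)
  expect_identical(de1, de2)
  expect_false(identical(
    de1[[1]]$log2fc,
    simulate_timecourse_de(n_genes = 400, n_timepoints = 2,
                           n_signature_genes = 30, seed = 6)[[1]]$log2fc))

  # extractor recovers >= 90% of planted genes at matching thresholds
  for (t in 1:2) {
    de <- de1[[t]]
    planted <- de$gene_id[abs(de$log2fc) >= 2 & de$p_adj < 0.05]
    sig <- extract_signature(de, lfc_min = 1, q_max = 0.05, min_size = 5)
    recovered <- intersect(planted, c(sig$up, sig$down))
    expect_gte(length(recovered) / length(planted), 0.9)
  }
})

test_that("an empty planted set makes the extractor fail loudly", {
  de <- simulate_timecourse_de(n_genes = 200, n_timepoints = 1,
                               n_signature_genes = 0, seed = 1)[[1]]
  expect_error(extract_signature(de, min_size = 10), "signature too small")
})

test_that("ortholog map fractions are honoured within rounding", {
  src <- sprintf("zf%03d", 1:200)
  map <- simulate_ortholog_map(src, frac_one_to_many = 0.1,
                               frac_unmapped = 0.05, seed = 2)
  fates <- table(factor(table(factor(map$source_gene, src)), c("0", "1", "2")))
  expect_identical(unname(fates[["0"]]), 10L)   # unmapped
  expect_identical(unname(fates[["2"]]), 20L)   # one-to-many
  expect_identical(unname(fates[["1"]]), 170L)

  bij <- simulate_ortholog_map(src, frac_one_to_many = 0, frac_unmapped = 0,
                               seed = 2)
  expect_identical(nrow(bij), 200L)
  expect_identical(anyDuplicated(bij$target_gene), 0L)

  none <- simulate_ortholog_map(src, frac_one_to_many = 0, frac_unmapped = 1,
                                seed = 2)
  expect_identical(nrow(none), 0L)
  sig <- signature("s", up = src[1:5], down = character(0))
  expect_error(translate_signature(sig, none), "untranslatable")

  expect_error(simulate_ortholog_map(src, frac_one_to_many = 0.6,
                                     frac_unmapped = 0.6), "<= 1")
  expect_identical(map, simulate_ortholog_map(src, frac_one_to_many = 0.1,
                                              frac_unmapped = 0.05, seed = 2))
})

test_that("every generated profile column is a permutation", {
  panel <- signature_panel(list(
    random_signature(sprintf("hs%03d", 1:50), 10, 10, seed = 4, name = "s1")
  ))
  cfg <- sim_config(n_genes = 300, n_compounds = 6, instances_per_compound = 2,
                    planted = data.frame(compound_id = "cmpd0002",
                                         direction = "positive",
                                         delta = 0.7, phi = 0.9),
                    seed = 9)
  pm <- simulate_profile_matrix(cfg, panel,
                                universe = c(sprintf("hs%03d", 1:50),
                                             sprintf("bg%03d", 1:250)))
  expect_identical(dim(pm$values), c(300L, 12L))
  for (j in seq_len(ncol(pm$values))) {
    expect_equal(sort(pm$values[, j]), 1:300, ignore_attr = TRUE)
  }
  expect_true(pm$is_ranks)
  # regenerating gives the identical matrix
  pm2 <- simulate_profile_matrix(cfg, panel,
                                 universe = c(sprintf("hs%03d", 1:50),
                                              sprintf("bg%03d", 1:250)))
  expect_identical(pm$values, pm2$values)
})

test_that("maximal planting pins signature genes to the extremes", {
  n <- 2000
  genes <- sprintf("hs%04d", 1:n)
  panel <- signature_panel(list(
    random_signature(genes, 20, 20, seed = 12, name = "s1")
  ))
  cfg <- sim_config(n_genes = n, n_compounds = 3, instances_per_compound = 1,
                    planted = data.frame(compound_id = "cmpd0001",
                                         direction = "positive",
                                         delta = 1, phi = 1),
                    seed = 21)
  pm <- simulate_profile_matrix(cfg, panel, universe = genes)
  sig <- panel$s1
  ranks1 <- pm$values[, "cmpd0001_i01"]
  names(ranks1) <- pm$genes
  expect_setequal(ranks1[sig$up], 1:20)            # up genes occupy the top
  expect_setequal(ranks1[sig$down], (n - 19):n)    # down genes the bottom
  res <- connectivity_score(sig, stats::setNames(as.integer(ranks1),
                                                 pm$genes))
  expect_lt(res$p_pos, 1e-6)
  expect_equal(res$p_neg, 1, tolerance = 1e-6)
})

test_that("recovery of the planted compound increases with delta and phi", {
  recover_rate <- function(delta, phi, seeds) {
    mean(vapply(seeds, function(s) {
      res <- run_synthetic_pipeline(
        seed = s, n_genes = 500, n_compounds = 20, n_timepoints = 2,
        n_signature_genes = 30,
        planted = data.frame(compound_id = "cmpd0005",
                             direction = "positive",
                             delta = delta, phi = phi))
      res$positive$compound_id[[1]] == "cmpd0005"
    }, logical(1)))
  }
  seeds <- 1:8
  weak <- recover_rate(0.15, 0.3, seeds)
  strong <- recover_rate(0.95, 1.0, seeds)
  mid <- recover_rate(0.95, 0.3, seeds)
  expect_gte(strong, mid)
  expect_gte(mid, weak)
  expect_identical(strong, 1)
})

test_that("simulate_fixture writes a consistent artifact set", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(n_genes = 300, n_compounds = 5, instances_per_compound = 1,
                    planted = data.frame(compound_id = "cmpd0002",
                                         direction = "positive",
                                         delta = 0.9, phi = 0.8),
                    seed = 3)
  fx <- simulate_fixture(dir, cfg, n_timepoints = 2, n_signature_genes = 25)
  expect_true(all(file.exists(unlist(fx$paths))))
  pm <- read_profile_matrix(fx$paths$matrix,
                            annotations = fx$paths$annotations)
  expect_true(pm$is_ranks)
  expect_equal(pm$values, fx$pm$values, ignore_attr = TRUE)
  panel <- gmt_to_panel(read_gmt(fx$paths$panel_hs))
  expect_identical(names(panel), names(fx$panel_hs))
  truth <- read.delim(fx$paths$truth)
  expect_identical(truth$compound_id, "cmpd0002")
})
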