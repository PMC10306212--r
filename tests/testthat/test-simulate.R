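test_that("identical configs regenerate byte-identical bundles", {
  cfg <- sim_config(seed = 99, n_genes = 30)
  b1 <- simulate_null(cfg)
  b2 <- simulate_null(cfg)
  expect_identical(b1$cohort$dosage, b2$cohort$dosage)
  expect_identical(b1$ctrl$tab, b2$ctrl$tab)
  expect_identical(b1$annotations, b2$annotations)
  d1 <- tempfile(); d2 <- tempfile()
  write_bundle(b1, d1); write_bundle(b2, d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
})

test_that("a written bundle round-trips through the readers", {
  cfg <- sim_config(seed = 7, n_cases = 10, n_genes = 25)
  bundle <- simulate_null(cfg)
  dir <- tempfile()
  paths <- write_bundle(bundle, dir)
  cohort <- read_case_vcf(paths$vcf)
  expect_equal(cohort$n_cases, 10L)
  expect_setequal(cohort$variants$variant_id,
                  bundle$cohort$variants$variant_id)
  ids <- rownames(cohort$dosage)
  expect_identical(cohort$dosage,
                   bundle$cohort$dosage[ids, cohort$sample_ids])
  ctrl <- read_control_summary(paths$controls, cfg$n_controls)
  m <- match(ctrl$tab$variant_id, bundle$ctrl$tab$variant_id)
  expect_identical(ctrl$tab$ac, bundle$ctrl$tab$ac[m])
  sets <- read_gmt(paths$gmt)
  expect_equal(length(sets$sets), 25L)
})

test_that("case carrier rate matches its Hardy-Weinberg expectation", {
  cfg <- sim_config(seed = 123, n_genes = 2000, n_cases = 38)
  bundle <- simulate_null(cfg)
  truth <- bundle$truth
  # per gene: P(a sample carries >= 1 alt) = 1 - prod (1 - f_j)^2
  p_gene <- vapply(split(truth$f, truth$gene),
                   function(f) 1 - prod((1 - f)^2), numeric(1))
  expected <- mean(p_gene)
  carriers <- vapply(split(seq_len(nrow(truth)), truth$gene), function(i) {
    ids <- truth$variant_id[i]
    mean(colSums(bundle$cohort$dosage[ids, , drop = FALSE]) >= 1)
  }, numeric(1))
  observed <- mean(carriers)
  mc_se <- stats::sd(carriers) / sqrt(length(carriers))
  expect_lt(abs(observed - expected), 3 * mc_se + 1e-6)
})

test_that("f = 0 lower bound keeps counts near zero and caps are honoured", {
  cfg <- sim_config(seed = 3, n_genes = 10, af_range = c(1e-12, 1e-11))
  bundle <- simulate_null(cfg)
  expect_true(all(bundle$ctrl$tab$ac == 0L))
  expect_true(all(bundle$cohort$dosage == 0L))
  expect_true(all(2 * bundle$ctrl$tab$n_hom <= bundle$ctrl$tab$ac))
})

test_that("control allele frequencies recover the truth with unit slope", {
  cfg <- sim_config(seed = 77, n_genes = 2500)
  bundle <- simulate_null(cfg)
  f_hat <- bundle$ctrl$tab$ac / bundle$ctrl$tab$an
  m <- match(bundle$ctrl$tab$variant_id, bundle$truth$variant_id)
  f_true <- bundle$truth$f[m]
  slope <- sum(f_true * f_hat) / sum(f_true^2)
  expect_lt(abs(slope - 1), 0.05)
})

test_that("alternative simulation enriches only the spiked genes", {
  cfg <- sim_config(seed = 11, n_genes = 50,
                    risk_genes = c(GENE0007 = 20),
                    risk_gene_af = list(GENE0007 = rep(0.001, 5)))
  bundle <- simulate_alternative(cfg)
  expect_setequal(unique(bundle$truth$gene[bundle$truth$enrichment > 1]),
                  "GENE0007")
  expect_equal(sum(bundle$truth$f[bundle$truth$gene == "GENE0007"]), 0.005)
  # spiked carrier rate is far above the null expectation 2*Sum(f)
  ids <- bundle$truth$variant_id[bundle$truth$gene == "GENE0007"]
  rate <- mean(colSums(bundle$cohort$dosage[ids, , drop = FALSE]) >= 1)
  expect_gt(rate, 0.02)
  # misconfigurations
  expect_error(simulate_alternative(sim_config(seed = 1, n_genes = 5,
                                               risk_genes = c(NOPE = 20))),
               "absent")
  expect_error(simulate_null(cfg), "risk_genes")
  expect_error(simulate_alternative(sim_config(seed = 1)), "non-empty")
})

test_that("coverage dropout blocks fail the joint gate contiguously", {
  cfg <- sim_config(seed = 13, n_genes = 40, coverage_dropout = 0.25)
  bundle <- simulate_null(cfg)
  retained <- joint_coverage_gate(bundle$case_cov, bundle$ctrl_cov, 0.9)
  # one contiguous retained block: genes 11..40
  expect_equal(length(retained), 1L)
  keys <- bundle$cohort$variants
  m <- match(keys$variant_id, bundle$truth$variant_id)
  gene_idx <- as.integer(sub("GENE", "", bundle$truth$gene[m]))
  expect_identical(in_retained(keys, retained), gene_idx > 10L)
})
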