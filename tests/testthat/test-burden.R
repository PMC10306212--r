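make_cohort <- function(dosage_rows, n_samples) {
  ids <- names(dosage_rows)
  d <- do.call(rbind, dosage_rows)
  rownames(d) <- ids
  structure(list(sample_ids = paste0("S", seq_len(n_samples)),
                 n_cases = n_samples,
                 variants = data.frame(variant_id = ids),
                 dosage = d),
            class = "CaseCohort")
}

make_ctrl <- function(ac, n_hom = 0L, n_controls = 56885L) {
  structure(list(n_controls = n_controls,
                 tab = data.frame(variant_id = names(ac),
                                  ac = unname(ac),
                                  n_hom = rep_len(n_hom, length(ac)),
                                  stringsAsFactors = FALSE)),
            class = "ControlSummary")
}

test_that("dominant case counting: carriers counted once, alleles summed", {
  # two distinct cases each het for a different variant of the same gene
  co <- make_cohort(list("v1" = c(1L, 0L, 0L), "v2" = c(0L, 1L, 0L)), 3)
  expect_equal(count_case_dominant(co, c("v1", "v2")),
               list(carriers = 2L, alleles = 2L))
  # one case het at two variants in the same gene
  co2 <- make_cohort(list("v1" = c(1L, 0L), "v2" = c(1L, 0L)), 2)
  expect_equal(count_case_dominant(co2, c("v1", "v2")),
               list(carriers = 1L, alleles = 2L))
  expect_equal(count_case_dominant(co2, "absent"),
               list(carriers = 0L, alleles = 0L))
})

test_that("control carrier proxy sums allele counts with a cohort cap", {
  ctrl <- make_ctrl(c(v1 = 317L, v2 = 67L))
  expect_equal(count_control_dominant(ctrl, c("v1", "v2")), 384L)
  expect_equal(count_control_dominant(ctrl, character()), 0L)
  # absent variants contribute zero
  expect_equal(count_control_dominant(ctrl, c("v1", "vX")), 317L)
  small <- make_ctrl(c(v1 = 90L), n_controls = 50L)
  expect_equal(count_control_dominant(small, "v1"), 50L)
})

test_that("recessive counts: dosage-2 cases incl. compound hets; control homs", {
  co <- make_cohort(list("v1" = c(2L, 1L, 0L), "v2" = c(0L, 1L, 0L)), 3)
  ctrl <- make_ctrl(c(v1 = 10L, v2 = 5L), n_hom = 0L)
  r <- count_recessive(co, ctrl, c("v1", "v2"))
  # sample 1 is hom-alt, sample 2 is a putative compound het
  expect_equal(r$case_count, 2L)
  expect_equal(r$control_count, 0L)
})

test_that("two-sided Fisher matches enumeration on derived examples", {
  # degenerate column
  expect_equal(fisher_two_sided(0, 38, 0, 56885), 1)
  # margins (10,10)x(5,15): every point probability <= observed, sum = 1
  expect_equal(fisher_two_sided(3, 7, 2, 8), 1)
  # sparse real-scale table, frozen from the enumeration oracle
  expect_equal(fisher_two_sided(2, 36, 15, 56870), oracle_fisher(2, 36, 15, 56870),
               tolerance = 1e-12)
  expect_error(fisher_two_sided(-1, 2, 3, 4), "non-negative")
  expect_error(fisher_two_sided(0, 0, 1, 5), "at least one")
})

test_that("Fisher is symmetric in group labels and agrees with fisher.test", {
  set.seed(31)
  for (i in 1:50) {
    a <- rpois(1, 2); b <- rpois(1, 10) + 1
    c_ <- rpois(1, 20); d <- rpois(1, 2000) + 1
    p1 <- fisher_two_sided(a, b, c_, d)
    expect_equal(p1, fisher_two_sided(c_, d, a, b), tolerance = 1e-12)
    expect_equal(p1, stats::fisher.test(matrix(c(a, b, c_, d), 2,
                                               byrow = TRUE))$p.value,
                 tolerance = 1e-9)
  }
})

test_that("p decreases in the case count above expectation, margins fixed", {
  # margins: carriers m, cases k, total N fixed; move a upward
  m <- 30; n <- 2000; k <- 40
  exp_a <- k * m / (m + n)
  a_vals <- ceiling(exp_a):min(k, m)
  p <- fisher_two_sided(a_vals, k - a_vals, m - a_vals, n - (k - a_vals))
  expect_true(all(diff(p) < 0))
})

test_that("gene burden restricts by case allele count and records n_tests", {
  counts <- data.frame(
    gene = c("INTU", "PEX7", "SOLO"),
    case_carriers = c(2L, 2L, 1L),
    case_alleles = c(2L, 2L, 1L),
    control_count = c(0L, 106L, 5L),
    n_cases = 38L, n_controls = 56885L)
  res1 <- gene_burden(counts, min_case_count = 1)
  expect_equal(nrow(res1), 3L)
  expect_true(all(res1$n_tests == 3L))
  res2 <- gene_burden(counts, min_case_count = 2)
  expect_setequal(res2$unit, c("INTU", "PEX7"))
  expect_true(all(res2$n_tests == 2L))
  # excluding a gene does not change another gene's raw p
  expect_equal(res2$p_raw[res2$unit == "INTU"],
               res1$p_raw[res1$unit == "INTU"])
  # zero-cell odds ratio is undefined, not corrected
  expect_true(is.na(res1$odds_ratio[res1$unit == "INTU"]))
  expect_warning(gene_burden(counts[0, ]), "no genes")
})
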