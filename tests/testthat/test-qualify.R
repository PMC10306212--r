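test_that("effective allele frequency follows source order with 0 fallback", {
  annos <- rbind(
    anno_row("1", 1, "A", "T", "PEX7", af_gnomad = 0.0007),
    anno_row("1", 2, "A", "T", "INTU"),                      # novel
    anno_row("1", 3, "A", "T", "G1", af_gnomad = 0.002, af_alfa = 0.0001),
    anno_row("1", 4, "A", "T", "G2", af_alfa = 0.0005)       # fallback
  )
  af <- effective_af(annos, c("af_gnomad_nfe", "af_alfa_eur"))
  expect_equal(af, c(0.0007, 0, 0.002, 0.0005))
  expect_error(effective_af(data.frame(af_gnomad_nfe = 1.2), "af_gnomad_nfe"),
               "\\[0,1\\]")
})

test_that("qualifying predicate combines coverage, PASS, AF and impact", {
  cfg1 <- qualify_config(af_max = 0.001)
  cfg2 <- qualify_config(af_max = 0.01)
  annos <- rbind(
    anno_row("1", 10, "A", "T", "PEX7", "stop_gained", 35, af_gnomad = 0.0007),
    anno_row("1", 20, "A", "T", "G1", "stop_gained", 35, af_gnomad = 0.005),
    anno_row("1", 30, "A", "T", "G2", "missense_variant", 28),
    anno_row("1", 40, "A", "T", "G3", "stop_gained", 12),
    anno_row("1", 50, "A", "T", "G4", "stop_gained", 35, filter = "RF")
  )
  expect_equal(qualify_variants(annos, cfg1),
               c(TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(qualify_variants(annos, cfg2),
               c(TRUE, TRUE, FALSE, FALSE, FALSE))
  # OR rule admits high-CADD missense
  cfg_or <- qualify_config(af_max = 0.01, combine_rule = "OR")
  expect_true(qualify_variants(annos[3, ], cfg_or))
  # AF boundary is inclusive
  at_bound <- anno_row("1", 60, "A", "T", "G5", af_gnomad = 0.001)
  expect_true(qualify_variants(at_bound, cfg1))
  # unknown consequence warns and is treated as non-impact
  odd <- anno_row("1", 70, "A", "T", "G6", "exotic_term", 35)
  expect_warning(q <- qualify_variants(odd, cfg2), "exotic_term")
  expect_false(q)
})

test_that("coverage gate participates in qualification", {
  cfg <- qualify_config()
  kept <- joint_coverage_gate(coverage_profile("1", 0, 15, 1),
                              coverage_profile("1", 0, 15, 1), 0.9)
  annos <- rbind(anno_row("1", 10, "A", "T", "G1"),
                 anno_row("1", 20, "A", "T", "G2"))
  expect_equal(qualify_variants(annos, cfg, kept), c(TRUE, FALSE))
})

test_that("SNP map keeps only case-carried qualifying variants per gene", {
  path <- write_vcf_fixture(vcf_text(c(
    vcf_row("1", 10, "A", "T", "PASS", c("0/1", "0/0")),
    vcf_row("1", 20, "G", "C", "PASS", c("0/0", "0/0")),   # no case carrier
    vcf_row("1", 30, "T", "A", "PASS", c("0/0", "1/1"))
  )))
  cohort <- read_case_vcf(path)
  annos <- rbind(
    anno_row("1", 10, "A", "T", "GENE_A"),
    anno_row("1", 20, "G", "C", "GENE_B"),
    anno_row("1", 30, "T", "A", "GENE_C"),
    anno_row("1", 30, "T", "A", "GENE_D")   # same variant, second gene
  )
  annos$filter <- NULL   # filter status joined from the cohort records
  cfg <- qualify_config()
  sm <- build_snp_map(cohort, annos, cfg)
  expect_s3_class(sm, "SnpMap")
  # gene whose only variant has all-zero case dosage is absent
  expect_false("GENE_B" %in% sm$gene)
  expect_equal(sm$variant_id[sm$gene == "GENE_A"], "1:10:A:T")
  # multi-gene variant appears under both genes
  expect_setequal(sm$gene[sm$variant_id == "1:30:T:A"],
                  c("GENE_C", "GENE_D"))
  expect_equal(attr(sm, "n_cases"), 2L)
})

test_that("qualifying sets are monotone in AF ceiling and coverage gate", {
  bundle <- simulate_null(sim_config(seed = 402, n_genes = 120,
                                     qualifying_fraction = 0.8,
                                     missing_af_fraction = 0.1,
                                     coverage_dropout = 0.2))
  retained <- joint_coverage_gate(bundle$case_cov, bundle$ctrl_cov, 0.9)
  maps <- lapply(c(0.001, 0.01), function(af) {
    build_snp_map(bundle$cohort, bundle$annotations,
                  qualify_config(af_max = af), retained)
  })
  key <- function(m) paste(m$gene, m$variant_id)
  # the very-rare map is a per-gene subset of the rare map
  expect_true(all(key(maps[[1]]) %in% key(maps[[2]])))
  # dropping the coverage gate never removes variants
  map_nogate <- build_snp_map(bundle$cohort, bundle$annotations,
                              qualify_config(af_max = 0.01), NULL)
  expect_true(all(key(maps[[2]]) %in% key(map_nogate)))
  expect_gt(nrow(map_nogate), nrow(maps[[2]]))  # dropout blocks do bite
  # permutation of annotation order does not change the map content
  perm <- bundle$annotations[sample(nrow(bundle$annotations)), ]
  map_perm <- build_snp_map(bundle$cohort, perm,
                            qualify_config(af_max = 0.01), retained)
  expect_setequal(key(map_perm), key(maps[[2]]))
})
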