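example_counts <- function() {
  data.frame(gene = c("CROT", "GSTK1", "EHHADH", "PEX7"),
             case_carriers = c(1L, 1L, 2L, 2L),
             case_alleles = c(1L, 1L, 2L, 2L),
             control_count = c(317L, 67L, 119L, 106L),
             n_cases = 38L, n_controls = 56885L)
}

test_that("restriction drops empty sets, keeps intersections, idempotent", {
  sets <- gene_set_collection(
    list(PEROXISOME = c("CROT", "GSTK1", "EHHADH", "PEX7", "PEX5"),
         UNRELATED = c("TP53", "BRCA1")),
    c(PEROXISOME = "KEGG", UNRELATED = "KEGG"))
  snp_genes <- c("CROT", "GSTK1", "EHHADH", "PEX7", "SYK")
  r <- restrict_sets(sets, snp_genes)
  expect_equal(names(r$sets), "PEROXISOME")
  expect_setequal(r$sets$PEROXISOME, c("CROT", "GSTK1", "EHHADH", "PEX7"))
  expect_equal(as.integer(attr(r, "n_sets_by_db")["KEGG"]), 1L)
  r2 <- restrict_sets(r, snp_genes)
  expect_equal(r2$sets, r$sets)
})

test_that("pathway counts are sums of member-gene counts", {
  counts <- example_counts()
  sets <- restrict_sets(
    gene_set_collection(list(PEROXISOME = c("CROT", "GSTK1", "EHHADH",
                                            "PEX7", "PEX5"))),
    counts$gene)
  pc <- aggregate_pathways(counts, sets)
  expect_equal(pc$case_count, 6L)
  expect_equal(pc$control_count, 609L)
  expect_false(pc$capped)
  # conservation against member genes, asserted cell by cell
  expect_equal(pc$case_count,
               sum(counts$case_carriers[counts$gene %in%
                                          sets$sets$PEROXISOME]))
  # a member gene without a count row is a consistency error
  bad_sets <- gene_set_collection(list(P = c("CROT", "MISSING")))
  expect_error(aggregate_pathways(counts, bad_sets), "MISSING")
})

test_that("zero-count genes never change a pathway p-value", {
  counts <- example_counts()
  counts0 <- rbind(counts,
                   data.frame(gene = "NULLGENE", case_carriers = 0L,
                              case_alleles = 0L, control_count = 0L,
                              n_cases = 38L, n_controls = 56885L))
  s1 <- gene_set_collection(list(P = counts$gene))
  s2 <- gene_set_collection(list(P = counts0$gene))
  p1 <- pathway_burden(aggregate_pathways(counts, s1))
  p2 <- pathway_burden(aggregate_pathways(counts0, s2))
  expect_equal(p1$p_raw, p2$p_raw, tolerance = 1e-15)
})

test_that("single-member pathway reproduces the gene-level p", {
  counts <- example_counts()
  sets <- gene_set_collection(list(ONLY_PEX7 = "PEX7"))
  pw <- pathway_burden(aggregate_pathways(counts, sets))
  gn <- gene_burden(counts)
  expect_equal(pw$p_raw, gn$p_raw[gn$unit == "PEX7"], tolerance = 1e-15)
})

test_that("case-side sums are capped at the cohort size with a warning", {
  counts <- data.frame(gene = paste0("G", 1:6),
                       case_carriers = rep(2L, 6), case_alleles = rep(2L, 6),
                       control_count = rep(10L, 6),
                       n_cases = 5L, n_controls = 1000L)
  sets <- gene_set_collection(list(BIG = counts$gene))
  expect_warning(pc <- aggregate_pathways(counts, sets), "capped")
  expect_equal(pc$case_count, 5L)
  expect_true(pc$capped)
  res <- pathway_burden(pc)
  expect_true(res$capped)
  expect_equal(res$a + res$b, 5L)
})

test_that("published example: pathway sums reproduce the printed pairs", {
  # per-pathway case/control totals as printed for each consistent arm
  printed <- list(
    gnomad_rare = list(
      "Olfactory transduction" = c(15, 4772),
      "Peroxisome" = c(6, 609),
      "FCERI mediated Ca+2 mobilization" = c(4, 90),
      "Antigen activates B Cell Receptor (BCR) leading to generation of second messengers" = c(4, 110),
      "FCGR activation" = c(3, 77),
      "DAP12 signaling" = c(2, 15)),
    exac_rare = list(
      "Olfactory transduction" = c(14, 2564),
      "Peroxisome" = c(6, 316)),
    gnomad_vrare = list(
      "Olfactory transduction" = c(6, 349),
      "Purine metabolism" = c(4, 274),
      "Post-translational protein phosphorylation" = c(3, 116),
      "Tryptophan metabolism" = c(4, 266),
      "Retinol metabolism" = c(4, 275),
      "Drug metabolism cytochrome p450" = c(4, 310)),
    exac_vrare = list(
      "Olfactory transduction" = c(6, 283),
      "Peroxisome" = c(6, 315),
      "Purine metabolism" = c(4, 151),
      "Post-translational protein phosphorylation" = c(3, 71)))
  arms <- list(gnomad_rare = c("gnomad", 0.01), exac_rare = c("exac", 0.01),
               gnomad_vrare = c("gnomad", 0.001),
               exac_vrare = c("exac", 0.001))
  for (arm in names(printed)) {
    pc <- lymphoid_example_pathway_counts(arms[[arm]][1],
                                          as.numeric(arms[[arm]][2]))
    for (pw in names(printed[[arm]])) {
      expect_equal(unname(unlist(
        pc[pc$pathway == pw, c("case_count", "control_count")])),
        printed[[arm]][[pw]],
        info = paste(arm, pw))
    }
  }
})
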