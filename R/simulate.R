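#' Simulation configuration
#'
#' Defines the study conditions emulated by the generator: a small
#' jointly-called case cohort (default 38 European cases) against a large
#' public control cohort summarized by allele counts (default 56,885,
#' gnomAD-exome NFE scale; 33,370 matches the ExAC arm). Variant site
#' frequencies follow a log-uniform spectrum over (1e-6, 0.01], qualifying
#' variants receive a high-impact consequence and CADD >= 20, and optional
#' risk genes multiply the per-variant case carrier probability.
#'
#' @param seed Integer seed; identical configs regenerate identical bundles.
#' @param n_cases Case cohort size (default 38).
#' @param n_controls Control cohort size (default 56885).
#' @param n_genes Number of simulated genes (default 200).
#' @param variants_per_gene Function `n -> integer vector` drawing the
#'   number of variant sites per gene (default `1 + Poisson(3)`, a realistic
#'   handful of rare qualifying sites per gene).
#' @param af_range Log-uniform allele-frequency spectrum bounds
#'   (default `c(1e-6, 0.01)`).
#' @param qualifying_fraction Share of variants given a high-impact
#'   consequence and CADD >= 20 (default 1: every simulated site is a
#'   candidate qualifying site; lower it to exercise the filters).
#' @param risk_genes Named numeric vector gene -> enrichment factor (>= 1)
#'   multiplying the per-variant case carrier probability.
#' @param risk_gene_af Optional named list gene -> per-variant frequency
#'   vector, fixing a risk gene's site frequencies (so that a spiked gene
#'   has a controlled total frequency).
#' @param coverage_dropout Fraction of genes whose region fails the joint
#'   coverage gate, placed as contiguous blocks (default 0).
#' @param missing_af_fraction Share of variants with an empty AF map,
#'   i.e. novel (default 0.05).
#' @return A list of class `SimConfig`.
#' @export
sim_config <- function(seed,
                       n_cases = 38,
                       n_controls = 56885,
                       n_genes = 200,
                       variants_per_gene = function(n) 1L + stats::rpois(n, 3),
                       af_range = c(1e-6, 0.01),
                       qualifying_fraction = 1,
                       risk_genes = numeric(),
                       risk_gene_af = list(),
                       coverage_dropout = 0,
                       missing_af_fraction = 0.05) {
  stopifnot(is.numeric(seed), length(seed) == 1,
            n_cases >= 1, n_controls >= 1, n_genes >= 1,
            af_range[1] > 0, af_range[2] <= 1, af_range[1] < af_range[2],
            qualifying_fraction >= 0, qualifying_fraction <= 1,
            coverage_dropout >= 0, coverage_dropout <= 1,
            missing_af_fraction >= 0, missing_af_fraction <= 1)
  if (length(risk_genes) && any(risk_genes < 1)) {
    stop("risk gene enrichment factors must be >= 1")
  }
  structure(list(seed = as.integer(seed), n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 n_genes = as.integer(n_genes),
                 variants_per_gene = variants_per_gene,
                 af_range = af_range,
                 qualifying_fraction = qualifying_fraction,
                 risk_genes = risk_genes,
                 risk_gene_af = risk_gene_af,
                 coverage_dropout = coverage_dropout,
                 missing_af_fraction = missing_af_fraction),
            class = "SimConfig")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Simulate a null input bundle
#'
#' Generates a complete analysis input bundle with no gene-disease
#' association: per variant site with frequency f, the control alternate
#' allele count is Binomial(2 * n_controls, f) and each case's dosage is
#' Binomial(2, f) (Hardy-Weinberg), independently of the controls (the case
#' and public control cohorts do not overlap). Annotations, coverage tracks
#' and the per-variant ground truth are produced alongside, in the exact
#' structures the pipeline reads.
#'
#' @param cfg A [sim_config()] with empty `risk_genes`.
#' @return A list of class `SimBundle`: `cohort` (`CaseCohort`), `ctrl`
#'   (`ControlSummary`), `annotations`, `case_cov`, `ctrl_cov`
#'   (`CoverageProfile`s), `truth` (per-variant frequency, gene, enrichment
#'   -- never read by the pipeline), `cfg`.
#' @export
simulate_null <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  if (length(cfg$risk_genes)) {
    stop("simulate_null requires an empty risk_genes map; ",
         "use simulate_alternative")
  }
  simulate_bundle(cfg)
}

#' Simulate an alternative (enriched) input bundle
#'
#' As [simulate_null()], but in each risk gene the per-variant case carrier
#' probability becomes `min(1, enrichment * 2f)` (controls are untouched).
#' Carrier probabilities exceeding 1 are capped with a warning. The ground
#' truth records which genes are enriched.
#'
#' @param cfg A [sim_config()] with non-empty `risk_genes`.
#' @return A `SimBundle`.
#' @export
simulate_alternative <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  if (length(cfg$risk_genes) == 0) {
    stop("simulate_alternative requires a non-empty risk_genes map")
  }
  simulate_bundle(cfg)
}

simulate_bundle <- function(cfg) {
  with_seed(cfg$seed, {
    genes <- sprintf("GENE%04d", seq_len(cfg$n_genes))
    missing_risk <- setdiff(names(cfg$risk_genes), genes)
    if (length(missing_risk)) {
      stop("risk gene(s) absent from simulated panel: ",
           paste(missing_risk, collapse = ", "))
    }
    n_var <- cfg$variants_per_gene(cfg$n_genes)
    # fixed per-site frequencies for risk genes, when requested
    for (g in names(cfg$risk_gene_af)) {
      n_var[match(g, genes)] <- length(cfg$risk_gene_af[[g]])
    }
    gene_of <- rep(genes, n_var)
    n_total <- length(gene_of)
    # each gene occupies a disjoint 10 kb block on chr1
    block <- rep(seq_len(cfg$n_genes), n_var)
    pos <- vapply(seq_len(n_total), function(i) {
      (block[i] - 1L) * 10000L + sample.int(9999L, 1L)
    }, integer(1))
    # unique positions within a gene block
    dup <- duplicated(paste(block, pos))
    while (any(dup)) {
      pos[dup] <- (block[dup] - 1L) * 10000L +
        vapply(seq_len(sum(dup)), function(i) sample.int(9999L, 1L), integer(1))
      dup <- duplicated(paste(block, pos))
    }
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n_total, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))

    f <- exp(stats::runif(n_total, log(cfg$af_range[1]),
                          log(cfg$af_range[2])))
    for (g in names(cfg$risk_gene_af)) {
      f[gene_of == g] <- cfg$risk_gene_af[[g]]
    }
    enrich <- rep(1, n_total)
    for (g in names(cfg$risk_genes)) {
      enrich[gene_of == g] <- cfg$risk_genes[[g]]
    }

    keys <- variant_key("1", pos, ref, alt)

    # case genotypes: HW under the null; carrier-probability model in
    # risk genes (dosage 1 with probability min(1, e * 2f))
    dosage <- matrix(0L, n_total, cfg$n_cases,
                     dimnames = list(keys$variant_id,
                                     sprintf("CASE%03d", seq_len(cfg$n_cases))))
    null_rows <- which(enrich == 1)
    if (length(null_rows)) {
      dosage[null_rows, ] <- stats::rbinom(length(null_rows) * cfg$n_cases,
                                           2L, rep(f[null_rows], cfg$n_cases))
    }
    alt_rows <- which(enrich > 1)
    if (length(alt_rows)) {
      pr <- pmin(1, enrich[alt_rows] * 2 * f[alt_rows])
      if (any(enrich[alt_rows] * 2 * f[alt_rows] > 1)) {
        warning("enrichment pushes a carrier probability above 1; capped")
      }
      dosage[alt_rows, ] <- stats::rbinom(length(alt_rows) * cfg$n_cases,
                                          1L, rep(pr, cfg$n_cases))
    }

    # control summary: independent binomial allele counts
    an <- rep(2L * cfg$n_controls, n_total)
    ac <- stats::rbinom(n_total, an, f)
    n_hom <- pmin(stats::rbinom(n_total, cfg$n_controls, f * f), ac %/% 2L)
    ctrl_tab <- data.frame(chrom = keys$chrom, pos = keys$pos,
                           ref = keys$ref, alt = keys$alt,
                           variant_id = keys$variant_id,
                           ac = ac, an = an, n_hom = n_hom,
                           filter = "PASS", stringsAsFactors = FALSE)
    ctrl <- structure(list(n_controls = cfg$n_controls, tab = ctrl_tab),
                      class = "ControlSummary")

    # annotations
    qual <- stats::runif(n_total) <= cfg$qualifying_fraction
    consequence <- ifelse(qual,
                          sample(impact_terms_default, n_total, replace = TRUE),
                          "missense_variant")
    cadd <- ifelse(qual, stats::runif(n_total, 20, 45),
                   stats::runif(n_total, 0, 19.99))
    af_missing <- stats::runif(n_total) < cfg$missing_af_fraction
    af_src <- ifelse(af_missing, NA_real_, f)
    annos <- data.frame(chrom = keys$chrom, pos = keys$pos, ref = keys$ref,
                        alt = keys$alt, variant_id = keys$variant_id,
                        gene = gene_of, consequence = consequence,
                        cadd_phred = round(cadd, 2),
                        af_gnomad_nfe = af_src, af_alfa_eur = NA_real_,
                        filter = "PASS", stringsAsFactors = FALSE)

    # coverage: whole panel covered, minus contiguous dropout blocks
    # (a prefix of gene blocks fails the case-side gate)
    n_drop <- floor(cfg$coverage_dropout * cfg$n_genes)
    span_end <- cfg$n_genes * 10000
    if (n_drop >= cfg$n_genes) {
      case_cov <- coverage_profile("1", 0, span_end, 0.5)
    } else if (n_drop > 0) {
      drop_end <- n_drop * 10000
      case_cov <- coverage_profile(c("1", "1"), c(0, drop_end),
                                   c(drop_end, span_end), c(0.5, 1))
    } else {
      case_cov <- coverage_profile("1", 0, span_end, 1)
    }
    ctrl_cov <- coverage_profile("1", 0, span_end, 0.98)

    cohort <- new_case_cohort(colnames(dosage),
                              data.frame(keys,
                                         filter = "PASS",
                                         stringsAsFactors = FALSE),
                              dosage)
    truth <- data.frame(variant_id = keys$variant_id, gene = gene_of,
                        f = f, enrichment = enrich,
                        qualifying = qual, stringsAsFactors = FALSE)
    structure(list(cohort = cohort, ctrl = ctrl, annotations = annos,
                   case_cov = case_cov, ctrl_cov = ctrl_cov,
                   truth = truth, cfg = cfg),
              class = "SimBundle")
  })
}

#' Write a simulated bundle to disk in the pipeline's input formats
#'
#' Emits `cases.vcf` (VCF v4.2), `controls.tsv`, `annotations.tsv`,
#' `case_coverage.tsv`, `control_coverage.tsv`, `sets.gmt` (one set per
#' simulated gene unless a collection is supplied) and `truth.tsv` (ground
#' truth sidecar, never read by the pipeline).
#'
#' @param bundle A `SimBundle`.
#' @param dir Output directory.
#' @param sets Optional `GeneSetCollection` to write as the GMT.
#' @return Invisibly, a named list of paths.
#' @export
write_bundle <- function(bundle, dir, sets = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  # VCF
  v <- bundle$cohort$variants
  d <- bundle$cohort$dosage
  gt <- matrix(c("0/0", "0/1", "1/1")[d + 1L], nrow = nrow(d))
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", bundle$cohort$sample_ids),
                 collapse = "\t"))
  body <- vapply(seq_len(nrow(v)), function(i) {
    paste(c(v$chrom[i], v$pos[i], ".", v$ref[i], v$alt[i], ".",
            v$filter[i], ".", "GT", gt[i, ]), collapse = "\t")
  }, character(1))
  ord <- order(v$chrom, v$pos, v$alt)
  paths$vcf <- file.path(dir, "cases.vcf")
  writeLines(c(hdr, body[ord]), paths$vcf)
  tsv <- function(x, name) {
    p <- file.path(dir, name)
    utils::write.table(x, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  paths$controls <- tsv(bundle$ctrl$tab[
    , c("chrom", "pos", "ref", "alt", "ac", "an", "n_hom", "filter")],
    "controls.tsv")
  paths$annotations <- tsv(bundle$annotations, "annotations.tsv")
  cov_cols <- c("chrom", "start", "end", "frac_over")
  paths$case_cov <- tsv(as.data.frame(bundle$case_cov)[, cov_cols],
                        "case_coverage.tsv")
  paths$ctrl_cov <- tsv(as.data.frame(bundle$ctrl_cov)[, cov_cols],
                        "control_coverage.tsv")
  if (is.null(sets)) {
    genes <- unique(bundle$truth$gene)
    gmt <- vapply(genes, function(g) paste(c(paste0("SET_", g), "na", g),
                                           collapse = "\t"), character(1))
  } else {
    gmt <- vapply(names(sets$sets), function(p) {
      paste(c(p, "na", sets$sets[[p]]), collapse = "\t")
    }, character(1))
  }
  paths$gmt <- file.path(dir, "sets.gmt")
  writeLines(gmt, paths$gmt)
  paths$truth <- tsv(bundle$truth, "truth.tsv")
  invisible(paths)
}
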