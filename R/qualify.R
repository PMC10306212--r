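#' Consequence vocabulary
#'
#' The controlled vocabulary of consequence terms the filters understand.
#' High-impact (predicted loss-of-function) terms form the default impact
#' set; the remainder are recognized but non-impact.
#' @name consequences
NULL

impact_terms_default <- c(
  "splice_acceptor_variant", "splice_donor_variant", "stop_gained",
  "frameshift_variant", "stop_lost", "start_lost"
)

consequence_vocabulary <- c(
  impact_terms_default,
  "missense_variant", "synonymous_variant", "inframe_deletion",
  "inframe_insertion", "splice_region_variant", "intron_variant",
  "5_prime_UTR_variant", "3_prime_UTR_variant", "upstream_gene_variant",
  "downstream_gene_variant", "intergenic_variant", "non_coding_transcript_variant"
)

#' Qualifying-variant filter configuration
#'
#' Bundles every threshold of the pre-burden filtration: deleteriousness
#' (CADD Phred), predicted-impact consequence terms, allele-frequency
#' ceiling with ordered source fallback, and the joint coverage gate
#' parameters.
#'
#' @param cadd_min Minimum CADD Phred score (default 20, the top 1% most
#'   deleterious substitutions).
#' @param impact_terms High-impact consequence set (default: splice
#'   acceptor/donor, stop-gain, frameshift, stop-lost, start-lost).
#' @param af_max Allele-frequency ceiling, inclusive (default 0.01; use
#'   0.001 for the very-rare arm).
#' @param af_source_order Ordered column names of AF sources in the
#'   annotation table; the first non-missing source wins, and a variant
#'   absent from all sources is treated as frequency 0 (novel).
#' @param combine_rule `"AND"` (default) requires both the CADD and the
#'   consequence condition; `"OR"` requires either.
#' @param depth_min Read-depth threshold for coverage fractions (strict >).
#' @param coverage_frac_min Minimum per-base fraction of samples covered
#'   above `depth_min`, inclusive (default 0.90).
#' @return A list of class `QualifyConfig`.
#' @export
qualify_config <- function(cadd_min = 20,
                           impact_terms = impact_terms_default,
                           af_max = 0.01,
                           af_source_order = c("af_gnomad_nfe", "af_alfa_eur"),
                           combine_rule = c("AND", "OR"),
                           depth_min = 10,
                           coverage_frac_min = 0.9) {
  combine_rule <- match.arg(combine_rule)
  stopifnot(af_max > 0, af_max <= 1,
            coverage_frac_min > 0, coverage_frac_min <= 1,
            length(af_source_order) >= 1, cadd_min >= 0, depth_min >= 0)
  structure(list(cadd_min = cadd_min, impact_terms = impact_terms,
                 af_max = af_max, af_source_order = af_source_order,
                 combine_rule = combine_rule, depth_min = depth_min,
                 coverage_frac_min = coverage_frac_min),
            class = "QualifyConfig")
}

#' Effective allele frequency with source fallback
#'
#' Returns, per variant, the first non-missing allele frequency along the
#' configured source order (e.g. control-matched European AF first, then the
#' ALFA European frequency); variants absent from every source are treated
#' as frequency 0 (novel).
#'
#' @param annos Annotation data.frame holding one column per AF source
#'   (missing values as `NA`).
#' @param af_source_order Ordered character vector of AF column names.
#' @return Numeric vector of frequencies in \[0,1\].
#' @export
effective_af <- function(annos, af_source_order) {
  present <- intersect(af_source_order, names(annos))
  if (length(present) == 0) return(rep(0, nrow(annos)))
  af <- rep(NA_real_, nrow(annos))
  for (src in present) {
    v <- as.numeric(annos[[src]])
    af <- ifelse(is.na(af), v, af)
  }
  af[is.na(af)] <- 0
  if (any(af < 0 | af > 1)) stop("allele frequencies must lie in [0,1]")
  af
}

#' Qualifying-variant predicate
#'
#' A variant qualifies iff it lies in a coverage-retained interval, has PASS
#' filter status, its effective allele frequency is at most `af_max`
#' (inclusive), and the deleteriousness rule holds: under `combine_rule =
#' "AND"`, CADD >= `cadd_min` AND consequence in the impact set; under
#' `"OR"`, either condition suffices. Consequence terms outside the declared
#' vocabulary raise a warning and are treated as non-impact.
#'
#' @param annos Annotation data.frame with columns `chrom`, `pos`, `ref`,
#'   `alt`, `gene`, `consequence`, `cadd_phred`, `filter` and AF source
#'   columns.
#' @param cfg A [qualify_config()].
#' @param retained `GRanges` of retained bases, or `NULL` to skip the gate.
#' @return Logical vector, one element per annotation row.
#' @export
qualify_variants <- function(annos, cfg, retained = NULL) {
  stopifnot(inherits(cfg, "QualifyConfig"))
  unknown <- setdiff(unique(annos$consequence), consequence_vocabulary)
  if (length(unknown)) {
    warning("unknown consequence term(s) treated as non-impact: ",
            paste(unknown, collapse = ", "))
  }
  covered <- in_retained(annos, retained)
  passed <- annos$filter == "PASS"
  af_ok <- effective_af(annos, cfg$af_source_order) <= cfg$af_max
  cadd_ok <- !is.na(annos$cadd_phred) & annos$cadd_phred >= cfg$cadd_min
  impact_ok <- annos$consequence %in% cfg$impact_terms
  deleterious <- if (cfg$combine_rule == "AND") cadd_ok & impact_ok
                 else cadd_ok | impact_ok
  covered & passed & af_ok & deleterious
}

#' Build the gene-to-qualifying-variant SNP map
#'
#' Joins annotations to the case cohort by variant key, applies
#' [qualify_variants()], and keeps only (gene, variant) pairs where at least
#' one case carries an alternate allele. Genes whose qualifying list is
#' empty are omitted entirely: only genes with one or more case variants are
#' analysed. A variant annotated to several genes appears under each.
#'
#' @param cohort A `CaseCohort`.
#' @param annos Annotation table (may hold several rows per variant, one per
#'   gene).
#' @param cfg A [qualify_config()].
#' @param retained Retained-interval `GRanges` or `NULL`.
#' @return A data.frame of class `SnpMap` with columns `gene`, `chrom`,
#'   `pos`, `ref`, `alt`, `variant_id`; attribute `n_cases`.
#' @export
build_snp_map <- function(cohort, annos, cfg, retained = NULL) {
  stopifnot(inherits(cohort, "CaseCohort"))
  if (!"variant_id" %in% names(annos)) {
    annos$variant_id <- paste(annos$chrom, annos$pos, annos$ref, annos$alt,
                              sep = ":")
  }
  if (!"filter" %in% names(annos)) {
    # filter status lives on the case records; join it in
    annos$filter <- cohort$variants$filter[
      match(annos$variant_id, cohort$variants$variant_id)]
    annos$filter[is.na(annos$filter)] <- "."
  }
  keep <- annos$variant_id %in% cohort$variants$variant_id
  annos <- annos[keep, , drop = FALSE]
  if (nrow(annos)) {
    q <- qualify_variants(annos, cfg, retained)
    annos <- annos[q, , drop = FALSE]
  }
  if (nrow(annos)) {
    alt_alleles <- rowSums(cohort$dosage[annos$variant_id, , drop = FALSE])
    annos <- annos[alt_alleles >= 1, , drop = FALSE]
  }
  annos <- annos[!duplicated(annos[, c("gene", "variant_id")]), , drop = FALSE]
  out <- annos[order(annos$gene, annos$chrom, annos$pos, annos$alt),
               c("gene", "chrom", "pos", "ref", "alt", "variant_id"),
               drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_cases") <- cohort$n_cases
  class(out) <- c("SnpMap", "data.frame")
  out
}
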