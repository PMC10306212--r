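#' Two-sided Fisher's exact test for 2x2 tables
#'
#' Conditional on both margins, the cell `a` follows a hypergeometric
#' distribution; the two-sided p-value is the sum of point probabilities of
#' every table (same margins) whose probability does not exceed that of the
#' observed table, with a small relative tolerance for floating-point ties
#' (symmetric tables commonly tie to within rounding).
#'
#' The table layout is `(a, b)` = case carriers / case non-carriers and
#' `(c, d)` = control carriers / control non-carriers; by symmetry of the
#' test the group labelling does not matter.
#'
#' @param a,b,c,d Non-negative integer vectors (recycled to common length).
#'   Each group must be non-empty: `a + b >= 1` and `c + d >= 1`.
#' @param rel_tol Relative tolerance for probability ties (default 1e-7).
#' @return Numeric vector of p-values in (0, 1].
#' @export
fisher_two_sided <- function(a, b, c, d, rel_tol = 1e-7) {
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(as.numeric(a), n); b <- rep_len(as.numeric(b), n)
  c <- rep_len(as.numeric(c), n); d <- rep_len(as.numeric(d), n)
  if (any(c(a, b, c, d) < 0) || any(is.na(c(a, b, c, d)))) {
    stop("table entries must be non-negative integers")
  }
  if (any(a + b < 1) || any(c + d < 1)) {
    stop("each margin group must contain at least one individual")
  }
  vapply(seq_len(n), function(i) {
    m <- a[i] + c[i]            # carriers total
    nn <- b[i] + d[i]           # non-carriers total
    k <- a[i] + b[i]            # cases total
    lo <- max(0, k - nn)
    hi <- min(k, m)
    x <- lo:hi
    probs <- stats::dhyper(x, m, nn, k)
    p_obs <- probs[x == a[i]]
    min(1, sum(probs[probs <= p_obs * (1 + rel_tol)]))
  }, numeric(1))
}

#' Dominant-model carrier counting in cases
#'
#' Under the dominant model an individual is a carrier if their summed
#' alternate-allele dosage across the unit's qualifying variants is at least
#' one; each individual is counted once regardless of how many qualifying
#' alleles they carry. The allele count is the plain dosage sum.
#'
#' @param cohort A `CaseCohort`.
#' @param variant_ids Qualifying variant ids for one gene.
#' @return List with `carriers` (individuals with dosage >= 1) and
#'   `alleles` (total alternate alleles).
#' @export
count_case_dominant <- function(cohort, variant_ids) {
  stopifnot(inherits(cohort, "CaseCohort"))
  ids <- intersect(variant_ids, rownames(cohort$dosage))
  if (length(ids) == 0) return(list(carriers = 0L, alleles = 0L))
  per_sample <- colSums(cohort$dosage[ids, , drop = FALSE])
  list(carriers = sum(per_sample >= 1L), alleles = as.integer(sum(per_sample)))
}

#' Dominant-model carrier proxy in summary-statistic controls
#'
#' Public controls provide allele counts, not genotypes; the carrier count
#' is approximated by the summed alternate allele count over the unit's
#' variants, capped at the cohort size. At qualifying frequencies (<= 1%)
#' double-carrier controls are negligible, so the sum is a tight proxy.
#' Variants absent from the summary contribute 0 (unobserved alleles are
#' omitted from gnomAD-style tables; the coverage gate has already ensured
#' the region was callable).
#'
#' @param ctrl A `ControlSummary`.
#' @param variant_ids Qualifying variant ids for one gene.
#' @return Integer control carrier count.
#' @export
count_control_dominant <- function(ctrl, variant_ids) {
  stopifnot(inherits(ctrl, "ControlSummary"))
  hit <- ctrl$tab$variant_id %in% variant_ids
  as.integer(min(sum(ctrl$tab$ac[hit]), ctrl$n_controls))
}

#' Recessive-model counts
#'
#' Cases: individuals whose summed dosage across the unit's variants is at
#' least two (homozygotes or putative compound heterozygotes). Controls:
#' summed homozygote counts from the summary (a compound-heterozygote
#' pooling proxy is deliberately not applied; phase is unknowable from
#' summary statistics), capped at the cohort size.
#'
#' @param cohort A `CaseCohort`.
#' @param ctrl A `ControlSummary`.
#' @param variant_ids Qualifying variant ids for one gene.
#' @return List with `case_count` and `control_count`.
#' @export
count_recessive <- function(cohort, ctrl, variant_ids) {
  ids <- intersect(variant_ids, rownames(cohort$dosage))
  case_count <- if (length(ids) == 0) 0L else {
    sum(colSums(cohort$dosage[ids, , drop = FALSE]) >= 2L)
  }
  hit <- ctrl$tab$variant_id %in% variant_ids
  list(case_count = as.integer(case_count),
       control_count = as.integer(min(sum(ctrl$tab$n_hom[hit]),
                                      ctrl$n_controls)))
}

#' Per-gene count table
#'
#' Tabulates, for every gene in the SNP map, the dominant-model case carrier
#' count, the case allele count and the control carrier proxy.
#'
#' @param snp_map A `SnpMap`.
#' @param cohort A `CaseCohort`.
#' @param ctrl A `ControlSummary`.
#' @return A data.frame with columns `gene`, `case_carriers`, `case_alleles`,
#'   `control_count`, `n_cases`, `n_controls`.
#' @export
gene_counts <- function(snp_map, cohort, ctrl) {
  genes <- sort(unique(snp_map$gene))
  rows <- lapply(genes, function(g) {
    ids <- snp_map$variant_id[snp_map$gene == g]
    cc <- count_case_dominant(cohort, ids)
    data.frame(gene = g, case_carriers = cc$carriers,
               case_alleles = cc$alleles,
               control_count = count_control_dominant(ctrl, ids),
               n_cases = cohort$n_cases, n_controls = ctrl$n_controls,
               stringsAsFactors = FALSE)
  })
  if (length(rows) == 0) {
    return(data.frame(gene = character(), case_carriers = integer(),
                      case_alleles = integer(), control_count = integer(),
                      n_cases = integer(), n_controls = integer()))
  }
  do.call(rbind, rows)
}

#' Gene-level burden test
#'
#' One two-sided Fisher's exact test per gene on the 2x2 table
#' (case carriers, case non-carriers, control carriers, control
#' non-carriers) under the dominant model (or recessive counts when
#' requested). Only genes whose case allele count reaches `min_case_count`
#' are tested; `min_case_count = 2` reproduces the "two or more variant
#' counts in cases" subset. `n_tests` records the number of genes tested in
#' this arm, for downstream Bonferroni correction.
#'
#' @param counts Gene count table from [gene_counts()] (or a compatible
#'   table, e.g. the bundled published example counts). For the recessive
#'   model supply recessive counts in `case_carriers`/`control_count`.
#' @param min_case_count Minimum case allele count, 1 or 2.
#' @param model `"dominant"` (default) or `"recessive"` (label only; the
#'   counting happens upstream).
#' @return A data.frame of class `BurdenResult` with columns `unit`, `a`,
#'   `b`, `c`, `d`, `odds_ratio`, `p_raw`, `n_tests`. The odds ratio
#'   `(a*d)/(b*c)` is descriptive; tables with a zero cell report `NA`
#'   (no continuity correction is applied).
#' @export
gene_burden <- function(counts, min_case_count = 1,
                        model = c("dominant", "recessive")) {
  model <- match.arg(model)
  stopifnot(min_case_count >= 1)
  keep <- counts$case_alleles >= min_case_count
  counts <- counts[keep, , drop = FALSE]
  if (nrow(counts) == 0) {
    warning("no genes reach min_case_count = ", min_case_count)
    return(empty_burden_result())
  }
  burden_from_counts(unit = counts$gene,
                     case_count = counts$case_carriers,
                     control_count = counts$control_count,
                     n_cases = counts$n_cases,
                     n_controls = counts$n_controls)
}

burden_from_counts <- function(unit, case_count, control_count,
                               n_cases, n_controls) {
  a <- as.integer(case_count)
  b <- as.integer(n_cases) - a
  c_ <- as.integer(control_count)
  d <- as.integer(n_controls) - c_
  or <- ifelse(b > 0 & c_ > 0, (a * as.numeric(d)) / (as.numeric(b) * c_),
               NA_real_)
  res <- data.frame(unit = unit, a = a, b = b, c = c_, d = d,
                    odds_ratio = or,
                    p_raw = fisher_two_sided(a, b, c_, d),
                    n_tests = length(unit),
                    stringsAsFactors = FALSE)
  res <- res[order(res$unit), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("BurdenResult", "data.frame")
  res
}

empty_burden_result <- function() {
  res <- data.frame(unit = character(), a = integer(), b = integer(),
                    c = integer(), d = integer(), odds_ratio = numeric(),
                    p_raw = numeric(), n_tests = integer())
  class(res) <- c("BurdenResult", "data.frame")
  res
}
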