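#' Build a coverage profile from per-interval fractions
#'
#' Coverage is stored as 0-based half-open intervals annotated with the
#' fraction of cohort samples covered above the depth threshold. Intervals
#' within a profile must not overlap.
#'
#' @param chrom Chromosome labels.
#' @param start 0-based interval starts.
#' @param end Interval ends (exclusive); `end > start`.
#' @param frac_over Fractions in \[0,1\].
#' @return A data.frame of class `CoverageProfile`.
#' @export
coverage_profile <- function(chrom, start, end, frac_over) {
  start <- as.numeric(start); end <- as.numeric(end)
  frac_over <- as.numeric(frac_over)
  stopifnot(length(chrom) == length(start), length(start) == length(end),
            length(end) == length(frac_over))
  if (any(end <= start)) stop("coverage intervals must satisfy end > start")
  if (any(frac_over < 0 | frac_over > 1)) {
    stop("frac_over must lie in [0, 1]")
  }
  prof <- data.frame(chrom = as.character(chrom), start = start, end = end,
                     frac_over = frac_over, stringsAsFactors = FALSE)
  gr <- profile_granges(prof)
  if (any(GenomicRanges::countOverlaps(gr, gr) > 1)) {
    stop("coverage intervals overlap within one profile")
  }
  prof <- prof[order(prof$chrom, prof$start), , drop = FALSE]
  rownames(prof) <- NULL
  class(prof) <- c("CoverageProfile", "data.frame")
  prof
}

# 0-based half-open -> GRanges (1-based closed)
profile_granges <- function(prof) {
  GenomicRanges::GRanges(
    seqnames = prof$chrom,
    ranges = IRanges::IRanges(start = prof$start + 1, end = prof$end),
    frac_over = prof$frac_over
  )
}

#' Per-base fraction of samples covered above a depth threshold
#'
#' Computes, for every base, the fraction of cohort samples whose read depth
#' strictly exceeds `depth_min` ("covered at > 10x"), and condenses runs of
#' equal fractions into a compact interval profile.
#'
#' @param depths Numeric matrix, bases x samples, of read depths (>= 0).
#' @param chrom Chromosome label per base (length `nrow(depths)`).
#' @param pos 1-based base position per base.
#' @param depth_min Depth threshold; a sample counts only if depth is
#'   strictly greater (default 10).
#' @return A `CoverageProfile` over the given bases.
#' @export
case_coverage_fraction <- function(depths, chrom, pos, depth_min = 10) {
  depths <- as.matrix(depths)
  if (ncol(depths) == 0) stop("empty sample set: no depth columns")
  if (any(depths < 0)) stop("depths must be non-negative")
  stopifnot(length(chrom) == nrow(depths), length(pos) == nrow(depths))
  frac <- rowMeans(depths > depth_min)
  ord <- order(chrom, pos)
  chrom <- as.character(chrom)[ord]; pos <- as.integer(pos)[ord]
  frac <- frac[ord]
  # merge adjacent bases with identical fraction into intervals
  new_run <- c(TRUE, chrom[-1] != chrom[-length(chrom)] |
                 pos[-1] != pos[-length(pos)] + 1L |
                 frac[-1] != frac[-length(frac)])
  run <- cumsum(new_run)
  first <- which(new_run)
  last <- c(first[-1] - 1L, length(run))
  coverage_profile(
    chrom = chrom[first],
    start = pos[first] - 1L,
    end = pos[last],
    frac_over = frac[first]
  )
}

#' Joint case/control coverage gate
#'
#' A base is retained iff the fraction of samples covered above the depth
#' threshold is at least `coverage_frac_min` in the cases AND in the
#' controls (threshold inclusive: "at least 90%"). Bases absent from either
#' profile are dropped.
#'
#' @param case_cov,control_cov `CoverageProfile` objects on a shared
#'   coordinate system.
#' @param coverage_frac_min Minimum fraction, default 0.9.
#' @return A `GRanges` of retained bases: minimal, sorted, reduced.
#' @export
joint_coverage_gate <- function(case_cov, control_cov,
                                coverage_frac_min = 0.9) {
  stopifnot(coverage_frac_min > 0, coverage_frac_min <= 1)
  ok <- function(prof) {
    keep <- prof$frac_over >= coverage_frac_min
    GenomicRanges::reduce(profile_granges(prof[keep, , drop = FALSE]))
  }
  GenomicRanges::reduce(GenomicRanges::intersect(ok(case_cov),
                                                 ok(control_cov)))
}

#' Which variant keys fall in retained intervals
#'
#' @param keys Variant key table (`chrom`, `pos`).
#' @param retained `GRanges` from [joint_coverage_gate()], or `NULL` to
#'   disable the coverage gate (all positions retained).
#' @return Logical vector, one element per key.
#' @export
in_retained <- function(keys, retained) {
  if (is.null(retained)) return(rep(TRUE, nrow(keys)))
  gr <- GenomicRanges::GRanges(keys$chrom,
                               IRanges::IRanges(keys$pos, keys$pos))
  GenomicRanges::countOverlaps(gr, retained) > 0
}
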