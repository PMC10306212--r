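#' Restrict gene sets to genes with case variants
#'
#' Intersects every set with the genes present in the SNP map (i.e. genes
#' that carry at least one qualifying variant in at least one case) and
#' drops sets whose intersection is empty. The surviving-set count per
#' database is the multiplicity denominator of the pathway arm.
#'
#' @param sets A `GeneSetCollection`.
#' @param genes Character vector of genes, or a `SnpMap` (its genes are
#'   used).
#' @return A restricted `GeneSetCollection`; attribute `n_sets_by_db` holds
#'   the per-database surviving-set counts.
#' @export
restrict_sets <- function(sets, genes) {
  stopifnot(inherits(sets, "GeneSetCollection"))
  if (inherits(genes, "SnpMap") || is.data.frame(genes)) {
    genes <- unique(genes$gene)
  }
  restr <- lapply(sets$sets, intersect, y = genes)
  keep <- lengths(restr) > 0
  out <- gene_set_collection(restr[keep], sets$database[keep],
                             sets$parent)
  attr(out, "n_sets_by_db") <- table(out$database)
  out
}

#' Aggregate per-gene counts into per-pathway counts
#'
#' Sums the case and control counts of every member gene present in the
#' count table, per pathway ("the variant counts were summed to obtain a
#' per-pathway rare variant count"). A gene belonging to several pathways
#' contributes to each. The case-side sum may double-count an individual
#' carrying variants in two member genes; for table validity the count is
#' capped at `n_cases` with a warning flag, and control counts are capped at
#' `n_controls`.
#'
#' @param counts Per-gene count table (columns `gene`, case count column,
#'   `control_count`, `n_cases`, `n_controls`).
#' @param sets A restricted `GeneSetCollection` (see [restrict_sets()]).
#' @param case_col Which case column to sum (default `"case_carriers"`;
#'   published per-gene tables use plain variant counts, pass the matching
#'   column).
#' @return A data.frame of class `PathwayCount` with columns `pathway`,
#'   `database`, `genes` (comma-joined contributing genes), `case_count`,
#'   `control_count`, `n_cases`, `n_controls`, `capped`.
#' @export
aggregate_pathways <- function(counts, sets, case_col = "case_carriers") {
  stopifnot(inherits(sets, "GeneSetCollection"))
  stopifnot(case_col %in% names(counts))
  n_cases <- if (nrow(counts)) counts$n_cases[1] else 0L
  n_controls <- if (nrow(counts)) counts$n_controls[1] else 0L
  rows <- lapply(names(sets$sets), function(p) {
    members <- sets$sets[[p]]
    hit <- counts$gene %in% members
    absent <- setdiff(members, counts$gene)
    if (length(absent)) {
      stop("pathway '", p, "': no counts for member gene(s) ",
           paste(absent, collapse = ", "),
           "; restrict sets to the SNP map first")
    }
    case_sum <- sum(counts[[case_col]][hit])
    ctrl_sum <- sum(counts$control_count[hit])
    capped <- case_sum > n_cases || ctrl_sum > n_controls
    if (case_sum > n_cases) {
      warning("pathway '", p, "': summed case count ", case_sum,
              " exceeds n_cases = ", n_cases, "; capped")
    }
    data.frame(pathway = p,
               database = unname(sets$database[p]),
               genes = paste(sort(counts$gene[hit]), collapse = ","),
               case_count = min(case_sum, n_cases),
               control_count = min(ctrl_sum, n_controls),
               n_cases = n_cases, n_controls = n_controls,
               capped = capped, stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(pathway = character(), database = character(),
               genes = character(), case_count = integer(),
               control_count = integer(), n_cases = integer(),
               n_controls = integer(), capped = logical())
  }
  out <- out[order(out$pathway), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("PathwayCount", "data.frame")
  out
}

#' Pathway-level burden test
#'
#' One two-sided Fisher's exact test per pathway on the summed counts.
#' `n_tests` pools every database tested in the arm (the multiplicity
#' correction runs over all pathways analysed together).
#'
#' @param pathway_counts A `PathwayCount` table from [aggregate_pathways()].
#' @return A `BurdenResult` data.frame with an extra `database` and `genes`
#'   column.
#' @export
pathway_burden <- function(pathway_counts) {
  if (nrow(pathway_counts) == 0) {
    warning("no pathways to test")
    res <- empty_burden_result()
    res$database <- character()
    res$genes <- character()
    return(res)
  }
  res <- burden_from_counts(unit = pathway_counts$pathway,
                            case_count = pathway_counts$case_count,
                            control_count = pathway_counts$control_count,
                            n_cases = pathway_counts$n_cases,
                            n_controls = pathway_counts$n_controls)
  m <- match(res$unit, pathway_counts$pathway)
  res$database <- pathway_counts$database[m]
  res$genes <- pathway_counts$genes[m]
  res$capped <- pathway_counts$capped[m]
  res
}
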