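#' Read a jointly-called multi-sample case VCF
#'
#' Parses a VCF (v4.x) of jointly-called case genotypes, splits multiallelic
#' records into biallelic ones, normalizes variant representation, drops
#' records whose FILTER is not in `keep_filter`, and codes per-sample
#' alternate-allele dosages from the GT field. Missing genotypes (`./.`) are
#' coded as dosage 0 (non-carrier), which is conservative for case counts.
#'
#' @param path Path to a VCF file (plain text or bgzipped).
#' @param keep_filter Character set of FILTER values to retain
#'   (default `"PASS"`).
#' @return An object of class `CaseCohort`: a list with `sample_ids`,
#'   `n_cases`, `variants` (normalized biallelic keys with their original
#'   FILTER status) and `dosage`, an integer matrix (variants x samples,
#'   rownames = `variant_id`) of alt-allele counts in \{0,1,2\}.
#' @export
read_case_vcf <- function(path, keep_filter = "PASS") {
  if (length(keep_filter) < 1) stop("keep_filter must be non-empty")
  if (!file.exists(path)) stop("VCF not found: ", path)
  validate_vcf_lines(path)
  v <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop("malformed VCF '", path, "': ", conditionMessage(e))
  )
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gt <- v@gt
  if (is.null(gt) || ncol(gt) < 2) {
    stop("VCF contains zero samples: ", path)
  }
  sample_ids <- colnames(gt)[-1]
  if (nrow(fix) == 0) {
    return(new_case_cohort(sample_ids, empty_variant_table(),
                           matrix(0L, 0, length(sample_ids),
                                  dimnames = list(NULL, sample_ids))))
  }
  fmt <- gt[, 1]
  gt_field <- function(row_fmt, row_vals) {
    keys <- strsplit(row_fmt, ":", fixed = TRUE)[[1]]
    gi <- match("GT", keys)
    if (is.na(gi)) return(rep(NA_character_, length(row_vals)))
    vapply(strsplit(row_vals, ":", fixed = TRUE), function(x) {
      if (length(x) >= gi) x[gi] else NA_character_
    }, character(1))
  }
  gts <- t(vapply(seq_len(nrow(gt)),
                  function(i) gt_field(fmt[i], gt[i, -1, drop = TRUE]),
                  character(length(sample_ids))))
  if (length(sample_ids) == 1L) gts <- matrix(gts, ncol = 1L)
  colnames(gts) <- sample_ids

  tab <- data.frame(
    chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT,
    filter = ifelse(is.na(fix$FILTER) | fix$FILTER == "", ".", fix$FILTER),
    row = seq_len(nrow(fix)),
    stringsAsFactors = FALSE
  )
  spl <- split_multiallelic(tab)
  # dosage of allele `allele_index` per sample from the original record's GT
  alleles <- gsub("[|]", "/", gts)
  dosage <- matrix(0L, nrow(spl), length(sample_ids),
                   dimnames = list(spl$variant_id, sample_ids))
  for (j in seq_len(nrow(spl))) {
    g <- strsplit(alleles[spl$row[j], ], "/", fixed = TRUE)
    dosage[j, ] <- vapply(g, function(x) {
      sum(x == as.character(spl$allele_index[j]), na.rm = TRUE)
    }, integer(1))
  }
  keep <- spl$filter %in% keep_filter
  spl <- spl[keep, , drop = FALSE]
  dosage <- dosage[keep, , drop = FALSE]
  if (anyDuplicated(spl$variant_id)) {
    # identical normalized key from separate records: merge by max dosage
    ids <- unique(spl$variant_id)
    dosage <- do.call(rbind, lapply(ids, function(id) {
      pmin(2L, colSums(dosage[spl$variant_id == id, , drop = FALSE]))
    }))
    rownames(dosage) <- ids
    spl <- spl[!duplicated(spl$variant_id), , drop = FALSE]
  }
  vars <- spl[, c("chrom", "pos", "ref", "alt", "variant_id", "filter")]
  rownames(vars) <- NULL
  new_case_cohort(sample_ids, vars, dosage)
}

validate_vcf_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#CHROM\t", lines)
  if (length(hdr) != 1) {
    stop("malformed VCF '", path, "': missing #CHROM header line")
  }
  n_fields <- length(strsplit(lines[hdr], "\t", fixed = TRUE)[[1]])
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  for (i in body) {
    nf <- length(strsplit(lines[i], "\t", fixed = TRUE)[[1]])
    if (nf != n_fields) {
      stop("malformed VCF '", path, "': line ", i, " has ", nf,
           " fields, expected ", n_fields)
    }
  }
  invisible(TRUE)
}

empty_variant_table <- function() {
  data.frame(chrom = character(), pos = integer(), ref = character(),
             alt = character(), variant_id = character(),
             filter = character(), stringsAsFactors = FALSE)
}

new_case_cohort <- function(sample_ids, variants, dosage) {
  structure(list(sample_ids = sample_ids,
                 n_cases = length(sample_ids),
                 variants = variants,
                 dosage = dosage),
            class = "CaseCohort")
}

#' @export
print.CaseCohort <- function(x, ...) {
  cat("CaseCohort:", x$n_cases, "samples,", nrow(x$variants),
      "biallelic variants\n")
  invisible(x)
}

#' Read a public-control per-variant summary table
#'
#' Control cohorts are represented by summary statistics only: per variant,
#' the alternate allele count (`ac`), total called alleles (`an`), homozygote
#' count (`n_hom`) and filter status, for a cohort of known size. Rows with a
#' non-PASS filter are dropped; multiallelic rows (comma-separated `alt` with
#' per-allele `ac`/`n_hom`) are split; keys are normalized exactly as case
#' keys are.
#'
#' @param path Tab-separated file with columns `chrom`, `pos`, `ref`, `alt`,
#'   `ac`, `an`, `n_hom`, `filter`.
#' @param n_controls Number of individuals in the control cohort.
#' @return An object of class `ControlSummary`: list with `n_controls` and
#'   `tab` (normalized per-variant summary rows).
#' @export
read_control_summary <- function(path, n_controls) {
  stopifnot(is.numeric(n_controls), n_controls >= 1)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("chrom", "pos", "ref", "alt", "ac", "an", "n_hom", "filter")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("control summary lacks columns: ",
                         paste(miss, collapse = ", "))
  tab$pos <- as.integer(tab$pos)
  tab$an <- as.integer(tab$an)
  tab$row <- seq_len(nrow(tab))
  spl <- split_multiallelic(tab, per_allele = c("ac", "n_hom"))
  spl$ac <- as.integer(spl$ac)
  spl$n_hom <- as.integer(spl$n_hom)
  bad <- spl$ac > spl$an | 2L * spl$n_hom > spl$ac | spl$ac < 0 | spl$n_hom < 0
  if (any(bad)) {
    stop("control summary row ", spl$row[which(bad)[1]],
         ": allele-count invariant violated (need n_hom*2 <= ac <= an)")
  }
  if (any(spl$an > 2 * n_controls)) {
    stop("control summary row ", spl$row[which(spl$an > 2 * n_controls)[1]],
         ": an exceeds 2 * n_controls")
  }
  spl <- spl[spl$filter == "PASS", , drop = FALSE]
  tabo <- spl[, c("chrom", "pos", "ref", "alt", "variant_id",
                  "ac", "an", "n_hom", "filter")]
  rownames(tabo) <- NULL
  structure(list(n_controls = as.integer(n_controls), tab = tabo),
            class = "ControlSummary")
}

#' @export
print.ControlSummary <- function(x, ...) {
  cat("ControlSummary:", x$n_controls, "controls,", nrow(x$tab),
      "PASS variants\n")
  invisible(x)
}

#' Read gene sets in GMT format
#'
#' One set per line: set name, description, then member gene symbols,
#' tab-separated. Duplicate genes within a line are deduplicated.
#'
#' @param path GMT file path.
#' @param database Label for the source database of every set in this file
#'   (`"KEGG"`, `"Reactome"`, `"Biocarta"`, or other).
#' @return A `GeneSetCollection`: list with `sets` (named list of character
#'   vectors), `database` (named character vector) and `parent` (named
#'   character vector of optional higher-level hierarchy labels).
#' @export
read_gmt <- function(path, database = "other") {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(gene_set_collection(list(), character()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(fields) < 3
  if (any(short)) {
    stop("GMT parse error at line ", which(short)[1],
         ": fewer than 3 fields")
  }
  nm <- vapply(fields, `[[`, character(1), 1)
  if (anyDuplicated(nm)) stop("duplicate set names in GMT: ",
                              nm[duplicated(nm)][1])
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nm
  gene_set_collection(sets, stats::setNames(rep(database, length(nm)), nm))
}

#' Construct a gene-set collection
#'
#' @param sets Named list of character vectors (non-empty gene sets).
#' @param database Named character vector of database labels (one per set).
#' @param parent Optional named character vector mapping set names to
#'   higher-level hierarchy labels (annotation only; low-level sets are the
#'   tested units).
#' @return A `GeneSetCollection`.
#' @export
gene_set_collection <- function(sets, database = NULL, parent = NULL) {
  if (is.null(database)) {
    database <- stats::setNames(rep("other", length(sets)), names(sets))
  }
  if (length(sets)) {
    stopifnot(!is.null(names(sets)), all(nzchar(names(sets))))
    if (any(lengths(sets) == 0)) stop("gene sets must be non-empty")
  }
  structure(list(sets = sets,
                 database = database[names(sets)],
                 parent = parent),
            class = "GeneSetCollection")
}

#' @export
print.GeneSetCollection <- function(x, ...) {
  cat("GeneSetCollection:", length(x$sets), "sets (",
      paste(names(table(x$database)), table(x$database), collapse = ", "),
      ")\n")
  invisible(x)
}

#' Read a coverage profile
#'
#' @param path Tab-separated file with columns `chrom`, `start` (0-based),
#'   `end` (exclusive) and `frac_over` (fraction of samples covered above
#'   the depth threshold, in \[0,1\]).
#' @return A data.frame coverage profile (class `CoverageProfile`).
#' @export
read_coverage_profile <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "frac_over")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("coverage file lacks columns: ",
                         paste(miss, collapse = ", "))
  coverage_profile(tab$chrom, tab$start, tab$end, tab$frac_over)
}

#' Write the three TRAPD-style analysis tables plus QQ data
#'
#' Writes `snp.tsv` (gene to comma-joined qualifying variant keys),
#' `counts.tsv` (per-gene case/control counts), `burden.tsv` (per-unit test
#' results) and, when `qq` is supplied, `qq.tsv`. Rows are ordered
#' lexicographically by unit name so reruns are byte-identical.
#'
#' @param snp_map A `SnpMap` (see [build_snp_map()]).
#' @param counts Gene count table (see [gene_counts()]).
#' @param results Burden result table (gene- or pathway-level).
#' @param out_dir Output directory (created if needed).
#' @param qq Optional QQ table from [qq_points()].
#' @return Invisibly, the paths written.
#' @export
write_outputs <- function(snp_map, counts, results, out_dir, qq = NULL) {
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  tsv <- function(d, f) {
    utils::write.table(d, file.path(out_dir, f), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    file.path(out_dir, f)
  }
  snp_tab <- if (nrow(snp_map)) {
    agg <- stats::aggregate(variant_id ~ gene, data = snp_map,
                            FUN = function(x) paste(sort(x), collapse = ","))
    names(agg) <- c("gene", "variants")
    agg[order(agg$gene), , drop = FALSE]
  } else {
    data.frame(gene = character(), variants = character())
  }
  p1 <- tsv(snp_tab, "snp.tsv")
  counts <- counts[order(counts$gene), , drop = FALSE]
  p2 <- tsv(counts, "counts.tsv")
  results <- results[order(results$unit), , drop = FALSE]
  p3 <- tsv(results, "burden.tsv")
  paths <- c(p1, p2, p3)
  if (!is.null(qq)) paths <- c(paths, tsv(qq, "qq.tsv"))
  invisible(paths)
}

#' Re-read a written count file
#'
#' @param path Path to a `counts.tsv` written by [write_outputs()] (or the
#'   bundled example count tables).
#' @return A data.frame of per-gene counts.
#' @export
read_counts_file <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
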