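#' Run the full burden analysis from a single configuration
#'
#' Orchestrates, per analysis arm (control set x allele-frequency ceiling):
#' the joint coverage gate, qualifying-variant filtration, gene-level counts
#' and Fisher burden tests (at minimum case allele counts 1 and 2),
#' pathway aggregation and tests, quantile-window inflation estimation,
#' multiplicative lambda and Bonferroni correction, and deterministic
#' tab-separated outputs. Re-running on identical inputs is byte-identical.
#'
#' The configuration is a YAML file (or an equivalent named list) with
#' fields:
#' \preformatted{
#' case_vcf: cases.vcf
#' annotations: annotations.tsv
#' case_coverage: case_coverage.tsv      # optional; omit to skip the gate
#' out_dir: results
#' gene_sets:                            # optional
#'   - {path: kegg.gmt, database: KEGG}
#' qualify: {cadd_min: 20, combine_rule: AND, coverage_frac_min: 0.9}
#' arms:
#'   - label: gnomad_rare
#'     control_summary: controls.tsv
#'     n_controls: 56885
#'     control_coverage: control_coverage.tsv   # optional
#'     af_max: 0.01
#'     af_source_order: [af_gnomad_nfe, af_alfa_eur]
#' }
#'
#' @param config Path to a YAML config file, or a named list.
#' @return Invisibly, a named list (one element per arm) of result lists:
#'   `snp_map`, `counts`, `gene_burden`, `gene_burden_min2`,
#'   `pathway_burden`, `lambda_gene`, `lambda_pathway`, `out_dir`.
#' @export
run_pipeline <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  for (field in c("case_vcf", "annotations", "out_dir")) {
    if (is.null(cfg[[field]])) stop("config lacks required field: ", field)
  }
  if (is.null(cfg$arms) || length(cfg$arms) == 0) {
    stop("config declares zero analysis arms")
  }
  qd <- cfg$qualify %||% list()
  log_lines <- c(
    paste0("rvburden ", as.character(utils::packageVersion("rvburden"))),
    paste0("R ", R.version.string),
    paste0("config thresholds: ",
           paste(names(qd), unlist(qd), sep = "=", collapse = " "))
  )
  cohort <- read_case_vcf(cfg$case_vcf)
  annos <- utils::read.delim(cfg$annotations, stringsAsFactors = FALSE)
  key <- normalize_variants(annos)
  annos$pos <- key$pos; annos$ref <- key$ref; annos$alt <- key$alt
  annos$variant_id <- key$variant_id
  case_cov <- if (!is.null(cfg$case_coverage)) {
    read_coverage_profile(cfg$case_coverage)
  } else NULL
  sets <- NULL
  if (!is.null(cfg$gene_sets)) {
    colls <- lapply(cfg$gene_sets, function(gs) {
      read_gmt(gs$path, database = gs$database %||% "other")
    })
    sets <- Reduce(function(x, y) {
      gene_set_collection(c(x$sets, y$sets), c(x$database, y$database))
    }, colls)
  }

  out <- list()
  for (arm in cfg$arms) {
    label <- arm$label %||% stop("every arm needs a label")
    message("arm '", label, "': af_max = ", arm$af_max)
    ctrl <- read_control_summary(arm$control_summary, arm$n_controls)
    qcfg <- do.call(qualify_config, c(
      qd[setdiff(names(qd), c("af_max", "af_source_order"))],
      list(af_max = arm$af_max %||% 0.01,
           af_source_order = arm$af_source_order %||%
             c("af_gnomad_nfe", "af_alfa_eur"))
    ))
    retained <- NULL
    if (!is.null(case_cov) && !is.null(arm$control_coverage)) {
      ctrl_cov <- read_coverage_profile(arm$control_coverage)
      retained <- joint_coverage_gate(case_cov, ctrl_cov,
                                      qcfg$coverage_frac_min)
    }
    snp_map <- build_snp_map(cohort, annos, qcfg, retained)
    counts <- gene_counts(snp_map, cohort, ctrl)
    res1 <- apply_corrections(gene_burden(counts, min_case_count = 1))
    res2 <- if (any(counts$case_alleles >= 2)) {
      apply_corrections(gene_burden(counts, min_case_count = 2))
    } else empty_corrected()
    arm_res <- list(snp_map = snp_map, counts = counts,
                    gene_burden = res1, gene_burden_min2 = res2,
                    lambda_gene = if (nrow(res1)) res1$lambda[1] else NA_real_)
    if (!is.null(sets)) {
      restr <- restrict_sets(sets, snp_map)
      pc <- aggregate_pathways(counts, restr)
      resp <- apply_corrections(pathway_burden(pc))
      arm_res$pathway_counts <- pc
      arm_res$pathway_burden <- resp
      arm_res$lambda_pathway <- if (nrow(resp)) resp$lambda[1] else NA_real_
    }
    arm_dir <- file.path(cfg$out_dir, label)
    qq <- if (nrow(res1)) {
      est <- suppressWarnings(estimate_lambda(res1$p_raw))
      est$qq
    } else NULL
    write_outputs(snp_map, counts, res1, arm_dir, qq = qq)
    utils::write.table(res2, file.path(arm_dir, "burden_min2.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(arm_res$pathway_burden)) {
      utils::write.table(
        arm_res$pathway_burden[order(arm_res$pathway_burden$unit), ],
        file.path(arm_dir, "pathway_burden.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
    arm_res$out_dir <- arm_dir
    out[[label]] <- arm_res
    log_lines <- c(log_lines, paste0(
      "arm ", label, ": genes=", nrow(res1),
      " genes_min2=", nrow(res2),
      " pathways=", if (is.null(arm_res$pathway_burden)) 0
                    else nrow(arm_res$pathway_burden),
      " lambda_gene=", format(arm_res$lambda_gene, digits = 6)))
  }
  lam <- do.call(rbind, lapply(names(out), function(l) {
    data.frame(arm = l,
               lambda_gene = out[[l]]$lambda_gene,
               lambda_pathway = out[[l]]$lambda_pathway %||% NA_real_)
  }))
  utils::write.table(lam, file.path(cfg$out_dir, "lambda_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(log_lines, file.path(cfg$out_dir, "run.log"))
  invisible(out)
}

empty_corrected <- function() {
  res <- empty_burden_result()
  res$lambda <- numeric(); res$p_lambda <- numeric()
  res$p_final <- numeric(); res$significant <- logical()
  res
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Human-readable summary of a pipeline run
#'
#' Prints, per arm: the number of units tested per class, the inflation
#' factors, and every unit significant after full correction (p_final <=
#' 0.05), or a statement that none is.
#'
#' @param results The list returned by [run_pipeline()].
#' @return Invisibly, a data.frame of significant units across arms.
#' @export
report_summary <- function(results) {
  sig_all <- list()
  for (label in names(results)) {
    arm <- results[[label]]
    cat("== arm:", label, "==\n")
    cat(sprintf("  genes tested: %d (min2 subset: %d); pathways: %s\n",
                nrow(arm$gene_burden), nrow(arm$gene_burden_min2),
                if (is.null(arm$pathway_burden)) "none"
                else nrow(arm$pathway_burden)))
    cat(sprintf("  lambda (gene): %s; lambda (pathway): %s\n",
                format(arm$lambda_gene, digits = 4),
                format(arm$lambda_pathway %||% NA, digits = 4)))
    for (cls in c("gene_burden", "gene_burden_min2", "pathway_burden")) {
      res <- arm[[cls]]
      if (is.null(res) || nrow(res) == 0) next
      sig <- res[res$significant, , drop = FALSE]
      if (nrow(sig) == 0) {
        cat("  ", cls, ": no significant units\n")
      } else {
        for (i in seq_len(nrow(sig))) {
          cat(sprintf("  %s: %s p_raw=%.3g p_final=%.3g\n",
                      cls, sig$unit[i], sig$p_raw[i], sig$p_final[i]))
        }
        sig$arm <- label; sig$class <- cls
        sig_all[[paste(label, cls)]] <-
          sig[, c("arm", "class", "unit", "p_raw", "p_final")]
      }
    }
  }
  invisible(if (length(sig_all)) do.call(rbind, sig_all) else
            data.frame(arm = character(), class = character(),
                       unit = character(), p_raw = numeric(),
                       p_final = numeric()))
}
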