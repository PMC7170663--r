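# End-to-end orchestration: counts -> filters -> usage/expression ->
# diversity statistics -> gene classification -> allelic divergence, plus
# the summary report and correlation tables.

#' Pipeline thresholds
#'
#' All tunable thresholds of the analysis with their default values:
#' `min_reads_expressed` (20 reads in every replicate), `min_reads_used`
#' (5 reads in some sample), `f1_min` (0.90 dominant usage), `f2_gap`
#' (0.20 rank-1/rank-2 gap), `switch_threshold` (0.50 usage difference),
#' `min_allelic` (10 allele-specific reads per allele per sample),
#' `max_inconsistency` (0.10 allelic-vs-combined usage gap),
#' `divergence_alpha` (BH-adjusted p < 0.05), `divergence_min_delta`
#' (allelic usage difference > 0.10), `cor_alpha` (0.05, high-confidence
#' correlation arm).
#'
#' @param ... named overrides of the defaults.
#' @return Named list of thresholds.
#' @export
apa_thresholds <- function(...) {
  th <- list(min_reads_expressed = 20L, min_reads_used = 5L, f1_min = 0.90,
             f2_gap = 0.20, switch_threshold = 0.50, min_allelic = 10L,
             max_inconsistency = 0.10, divergence_alpha = 0.05,
             divergence_min_delta = 0.10, cor_alpha = 0.05)
  ov <- list(...)
  bad <- setdiff(names(ov), names(th))
  if (length(bad)) stop("unknown threshold(s): ", paste(bad, collapse = ", "))
  th[names(ov)] <- ov
  th
}

#' Run the full APA analysis pipeline
#'
#' Executes, in order: expression and used-PAS filtering, usage and RPM
#' quantification, dominant/major PAS labelling, diversity statistics
#' (Shannon index, mock-adjusted variability, switch scores), functional
#' gene classification, and — when allele-specific reads are present —
#' allelic usage filtering, cis-divergence calling and divergence classes.
#'
#' @param counts long counts `data.frame`.
#' @param annotations PAS annotation `data.frame`.
#' @param exclusion_list gene ids excluded from allelic analyses.
#' @param thresholds list from [apa_thresholds()].
#' @param n_mock mock iterations for adjusted statistics (default 100).
#' @param seed master integer seed for every stochastic stage.
#' @param brain_tissues labels counted as brain for the brain-specific F2
#'   flag.
#' @return An object of class `apa_report`.
#' @export
run_pipeline <- function(counts, annotations, exclusion_list = character(),
                         thresholds = apa_thresholds(), n_mock = 100L,
                         seed = 1L, brain_tissues = c("COR", "CER")) {
  validate_counts(counts)
  validate_annotations(annotations)

  expressed <- filter_expressed_genes(counts,
                                      min_reads = thresholds$min_reads_expressed)
  expressed_any <- sort(unique(unlist(expressed, use.names = FALSE)))
  if (!length(expressed_any)) stop("stage quantify: no expressed genes")
  used <- filter_used_pas(counts, min_reads = thresholds$min_reads_used)
  used <- used[used$gene_id %in% expressed_any, , drop = FALSE]
  cc <- restrict_to_used(counts[counts$gene_id %in% expressed_any, ,
                                drop = FALSE], used)

  usage_tissue <- compute_usage(cc, used, scope = "tissue")
  expression <- compute_expression(cc)
  dm <- dominant_and_major_pas(usage_tissue, expressed, annotations)
  stats_out <- diversity_stats(cc, used, expressed, annotations,
                               n_mock = n_mock, seed = seed)
  classification <- classify_genes(
    dm$dominant, dm$genes, stats_out, usage_tissue, expression, expressed,
    f1_min = thresholds$f1_min, f2_gap = thresholds$f2_gap,
    switch_threshold = thresholds$switch_threshold,
    cor_alpha = thresholds$cor_alpha, brain_tissues = brain_tissues)

  allelic <- NULL
  has_allelic <- any(counts$channel %in% c("B6", "SPR") & counts$count > 0)
  if (has_allelic) {
    af <- allelic_usage_with_filters(
      cc, exclusion_list = exclusion_list, annotations = annotations,
      min_allelic = thresholds$min_allelic,
      max_inconsistency = thresholds$max_inconsistency)
    if (nrow(af$testable)) {
      dv <- call_divergence(af, alpha = thresholds$divergence_alpha,
                            min_delta = thresholds$divergence_min_delta)
      allelic <- list(filtered = af, calls = dv$calls, genes = dv$genes,
                      classes = classify_divergence(dv$genes),
                      expression_divergence =
                        allelic_expression_divergence(cc))
    } else {
      message("allelic stage skipped: no gene x tissue passes the filters")
    }
  } else {
    message("allelic stage skipped: no allele-specific reads")
  }

  gi <- dm$genes
  n_exp <- length(expressed_any)
  n_single <- sum(gi$pas_class == "single")
  n_multi <- sum(gi$pas_class == "multi")
  grp <- table(factor(classification$group, levels = c("F1", "F2", "FU")))
  n_switched <- sum(classification$switched)
  n_fun <- sum(classification$functional_type)
  smry <- list(
    n_expressed = n_exp, n_single_pas = n_single, n_multi_pas = n_multi,
    pct_single_pas = 100 * n_single / n_exp,
    n_F1 = as.integer(grp[["F1"]]), n_F2 = as.integer(grp[["F2"]]),
    n_FU = as.integer(grp[["FU"]]),
    pct_F1 = 100 * grp[["F1"]] / n_multi,
    pct_F2 = 100 * grp[["F2"]] / n_multi,
    pct_FU = 100 * grp[["FU"]] / n_multi,
    n_switched = n_switched,
    n_functional = n_fun, pct_functional = 100 * n_fun / n_multi,
    n_high_confidence = sum(classification$high_confidence),
    n_brain_specific_f2 = sum(classification$brain_specific_f2))
  if (!is.null(allelic)) {
    smry$n_testable_gene_tissues <- nrow(allelic$genes)
    smry$n_divergent_gene_tissues <- sum(allelic$genes$divergent)
    smry$pct_divergent_gene_tissues <-
      100 * sum(allelic$genes$divergent) / nrow(allelic$genes)
    cls <- table(factor(allelic$classes$class,
                        levels = c("non_divergent", "some_divergent",
                                   "all_divergent")))
    smry$n_non_divergent <- as.integer(cls[["non_divergent"]])
    smry$n_some_divergent <- as.integer(cls[["some_divergent"]])
    smry$n_all_divergent <- as.integer(cls[["all_divergent"]])
  }

  structure(list(
    summary = smry,
    thresholds = c(thresholds, list(n_mock = n_mock, seed = seed,
                                    brain_tissues = brain_tissues)),
    expressed = expressed, used = used, usage_tissue = usage_tissue,
    expression = expression, dominant = dm$dominant, gene_info = dm$genes,
    stats = stats_out, classification = classification, allelic = allelic,
    tissues = sort(unique(counts$tissue))), class = "apa_report")
}

#' @export
print.apa_report <- function(x, ...) {
  s <- x$summary
  cat("APA analysis report\n")
  cat(sprintf("  tissues: %s\n", paste(x$tissues, collapse = ", ")))
  cat(sprintf("  expressed genes: %d (single-PAS %d = %.1f%%, multi-PAS %d)\n",
              s$n_expressed, s$n_single_pas, s$pct_single_pas, s$n_multi_pas))
  cat(sprintf("  groups: F1 %d (%.1f%%), F2 %d (%.1f%%), FU %d (%.1f%%)\n",
              s$n_F1, s$pct_F1, s$n_F2, s$pct_F2, s$n_FU, s$pct_FU))
  cat(sprintf("  switched %d; functional type %d (%.1f%%); high-confidence %d\n",
              s$n_switched, s$n_functional, s$pct_functional,
              s$n_high_confidence))
  if (!is.null(s$n_testable_gene_tissues)) {
    cat(sprintf("  allelic: %d testable gene x tissues, %d divergent (%.1f%%)\n",
                s$n_testable_gene_tissues, s$n_divergent_gene_tissues,
                s$pct_divergent_gene_tissues))
  }
  invisible(x)
}

#' @export
summary.apa_report <- function(object, ...) object$summary

#' Write an APA report to disk
#'
#' Emits per-stage TSVs, a JSON summary (including every threshold actually
#' used) and, when the allelic stage ran, the divergence tables.
#'
#' @param report an `apa_report`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_apa_report <- function(report, dir) {
  stopifnot(inherits(report, "apa_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wt <- function(df, name) {
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wt(report$usage_tissue, "usage_tissue.tsv")
  wt(report$expression$tissue_rpm, "expression_tissue_rpm.tsv")
  wt(report$dominant, "dominant_pas.tsv")
  wt(report$gene_info, "gene_info.tsv")
  wt(report$stats$diversity, "diversity.tsv")
  wt(report$stats$switch, "switch_scores.tsv")
  wt(report$classification, "classification.tsv")
  if (!is.null(report$allelic)) {
    wt(report$allelic$calls, "divergence_calls.tsv")
    wt(report$allelic$classes, "divergence_classes.tsv")
    wt(report$allelic$expression_divergence, "expression_divergence.tsv")
  }
  jsonlite::write_json(list(summary = report$summary,
                            thresholds = report$thresholds),
                       file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Spearman correlation report
#'
#' The correlation tables behind the headline observations: per tissue,
#' rho(expression, dominant usage) for all multi-PAS genes and for the
#' strata with dominant usage >= 0.9 and < 0.9; per tissue and group,
#' rho(Shannon index, adjusted variability); per tissue pair, rho(delta
#' major-PAS usage, delta log2 expression). P-values at or above 0.01 are
#' flagged as not significant.
#'
#' @param report an `apa_report`.
#' @return `data.frame` with columns `type`, `tissue` (or `pair`),
#'   `stratum`, `n`, `rho`, `p`, `significant`.
#' @export
correlation_report <- function(report) {
  rows <- list()
  add <- function(type, tissue, stratum, x, y) {
    keep <- !is.na(x) & !is.na(y)
    n <- sum(keep)
    if (n >= 3L && stats::sd(x[keep]) > 0 && stats::sd(y[keep]) > 0) {
      ct <- suppressWarnings(stats::cor.test(x[keep], y[keep],
                                             method = "spearman"))
      rows[[length(rows) + 1L]] <<- data.frame(
        type = type, tissue = tissue, stratum = stratum, n = n,
        rho = unname(ct$estimate), p = ct$p.value,
        significant = ct$p.value < 0.01, stringsAsFactors = FALSE)
    }
  }
  multi <- report$gene_info$gene_id[report$gene_info$pas_class == "multi"]
  dom <- report$dominant[report$dominant$gene_id %in% multi, , drop = FALSE]
  rpm <- report$expression$tissue_rpm
  rkey <- paste(rpm$gene_id, rpm$tissue)
  div <- report$stats$diversity
  dkey <- paste(div$gene_id, div$tissue)
  grp <- report$classification$group[
    match(dom$gene_id, report$classification$gene_id)]

  for (t in report$tissues) {
    sel <- dom$tissue == t
    if (!any(sel)) next
    e <- log2(rpm$rpm[match(paste(dom$gene_id[sel], t), rkey)] + 1)
    u <- dom$dominant_usage[sel]
    add("expression_vs_dominant_usage", t, "all", e, u)
    add("expression_vs_dominant_usage", t, "dpu_ge_0.9", e[u >= 0.9],
        u[u >= 0.9])
    add("expression_vs_dominant_usage", t, "dpu_lt_0.9", e[u < 0.9],
        u[u < 0.9])
    dsel <- div$gene_id %in% multi & div$tissue == t
    add("shannon_vs_adjusted_variability", t, "all", div$shannon[dsel],
        div$adjusted_var[dsel])
    for (g in c("F1", "F2", "FU")) {
      gg <- report$classification$gene_id[report$classification$group == g]
      gsel <- dsel & div$gene_id %in% gg
      add("shannon_vs_adjusted_variability", t, g, div$shannon[gsel],
          div$adjusted_var[gsel])
    }
  }
  # per tissue pair: major-usage change vs expression change
  ukey <- paste(report$usage_tissue$gene_id, report$usage_tissue$tissue,
                report$usage_tissue$pas_id)
  major <- report$gene_info$major_pas[match(multi, report$gene_info$gene_id)]
  tt <- report$tissues
  if (length(tt) >= 2L) {
    pr <- utils::combn(length(tt), 2L)
    for (i in seq_len(ncol(pr))) {
      a <- tt[pr[1L, i]]
      b <- tt[pr[2L, i]]
      both <- multi %in% report$expressed[[a]] & multi %in% report$expressed[[b]]
      if (!any(both)) next
      g <- multi[both]
      mj <- major[both]
      ua <- report$usage_tissue$usage[match(paste(g, a, mj), ukey)]
      ub <- report$usage_tissue$usage[match(paste(g, b, mj), ukey)]
      ua[is.na(ua)] <- 0
      ub[is.na(ub)] <- 0
      ea <- log2(rpm$rpm[match(paste(g, a), rkey)] + 1)
      eb <- log2(rpm$rpm[match(paste(g, b), rkey)] + 1)
      add("delta_major_usage_vs_delta_expression", paste(a, b, sep = ":"),
          "all", ua - ub, ea - eb)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
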