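# Partition multi-PAS genes into functional groups and derive candidate sets.
#
# F1: one tightly dominant PAS (usage >= 90%) in every expressing tissue.
# F2: some tissue where the rank-2 PAS trails the dominant PAS by <= 20%.
# FU: the remaining multi-PAS genes. Switched genes move one PAS by >= 50%
# between two tissues (mock-adjusted switch score by default). "Functional
# type" = F2 genes plus switched FU genes; a high-confidence subset requires
# expression support for the secondary PAS.

#' Classify multi-PAS genes into F1 / F2 / FU
#'
#' F1 iff dominant usage >= `f1_min` in every expressing tissue; else F2 iff
#' in at least one expressing tissue the dominant-minus-rank-2 usage gap is
#' <= `f2_gap`; else FU. (F1 takes precedence; with the default thresholds a
#' gene can never satisfy both.)
#'
#' @param dominant gene x tissue dominant/rank-2 table from
#'   [dominant_and_major_pas()].
#' @param gene_info per-gene table from the same call (supplies `pas_class`).
#' @param f1_min dominant-usage threshold (default 0.90, inclusive).
#' @param f2_gap rank-1/rank-2 usage-gap threshold (default 0.20, inclusive).
#' @return `data.frame` per multi-PAS gene: `group` (F1/F2/FU), `f2_tissues`
#'   (comma-joined tissues meeting the F2 criterion), `f2_pas` (rank-2 PAS in
#'   the tissue with the smallest gap).
#' @export
classify_f1_f2_fu <- function(dominant, gene_info, f1_min = 0.90,
                              f2_gap = 0.20) {
  multi <- gene_info$gene_id[gene_info$pas_class == "multi"]
  d <- dominant[dominant$gene_id %in% multi, , drop = FALSE]
  rows <- lapply(split(d, d$gene_id), function(ch) {
    gap <- ch$dominant_usage - ifelse(is.na(ch$rank2_usage), 0, ch$rank2_usage)
    f2_hit <- !is.na(ch$rank2_usage) & gap <= f2_gap
    grp <- if (all(ch$dominant_usage >= f1_min)) {
      "F1"
    } else if (any(f2_hit)) "F2" else "FU"
    best <- if (any(f2_hit)) which.min(ifelse(f2_hit, gap, Inf)) else NA_integer_
    data.frame(
      gene_id = ch$gene_id[1L], group = grp,
      f2_tissues = if (any(f2_hit)) paste(ch$tissue[f2_hit], collapse = ",")
      else NA_character_,
      f2_pas = if (!is.na(best)) ch$rank2_pas[best] else NA_character_,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Flag switched genes
#'
#' Switched iff the switch score (maximum between-tissue PAS usage
#' difference, mock-adjusted by default) is at least `threshold`.
#'
#' @param switch_scores per-gene switch-score table from [diversity_stats()]
#'   (columns `gene_id`, `switch_score`).
#' @param threshold usage-difference threshold (default 0.50, inclusive).
#' @return Logical vector named by gene id (`NA` scores are not switched).
#' @export
flag_switched <- function(switch_scores, threshold = 0.50) {
  sw <- !is.na(switch_scores$switch_score) &
    switch_scores$switch_score >= threshold
  stats::setNames(sw, switch_scores$gene_id)
}

#' Functional-type and high-confidence flags
#'
#' Functional type = F2 genes plus switched FU genes. The secondary PAS is
#' the rank-2 PAS of the tissue meeting the F2 criterion (for F2 genes) or
#' the most-changing PAS between the switch tissue pair (for switched FU
#' genes). A functional-type gene is high-confidence iff either (a) Spearman
#' rho between tissue expression (RPM) and secondary-PAS usage across >= 3
#' expressing tissues is positive with p < 0.05, or (b) the gene's RPM
#' exceeds the median RPM of expressed genes in the tissue where the
#' secondary PAS peaks.
#'
#' @param groups F1/F2/FU table from [classify_f1_f2_fu()].
#' @param switched named logical vector from [flag_switched()].
#' @param usage_tissue tissue-scope usage table.
#' @param expression result of [compute_expression()].
#' @param expressed per-tissue expressed-gene sets.
#' @param switch_table per-gene switch table (columns `gene_id`, `tissue_a`,
#'   `tissue_b`) used to locate the switch PAS.
#' @param cor_alpha p-value threshold of the correlation arm (default 0.05).
#' @return `data.frame` per multi-PAS gene: `functional_type`,
#'   `secondary_pas`, `high_confidence`, `hc_arm` ("correlation", "median" or
#'   `NA`).
#' @export
functional_and_high_confidence <- function(groups, switched, usage_tissue,
                                           expression, expressed,
                                           switch_table, cor_alpha = 0.05) {
  tiss_rpm <- expression$tissue_rpm
  # per-tissue median RPM over expressed genes
  med_rpm <- vapply(names(expressed), function(t) {
    r <- tiss_rpm$rpm[tiss_rpm$tissue == t &
                        tiss_rpm$gene_id %in% expressed[[t]]]
    if (length(r)) stats::median(r) else NA_real_
  }, 0)

  u_key <- paste(usage_tissue$gene_id, usage_tissue$tissue, usage_tissue$pas_id)
  r_key <- paste(tiss_rpm$gene_id, tiss_rpm$tissue)
  sw_tab <- switch_table[match(groups$gene_id, switch_table$gene_id), ,
                         drop = FALSE]

  out <- groups[, "gene_id", drop = FALSE]
  out$functional_type <- groups$group == "F2" |
    (groups$group == "FU" & switched[groups$gene_id] %in% TRUE)
  out$secondary_pas <- NA_character_
  out$high_confidence <- FALSE
  out$hc_arm <- NA_character_

  for (i in which(out$functional_type)) {
    g <- groups$gene_id[i]
    sec <- groups$f2_pas[i]
    if (is.na(sec)) {
      # switched FU gene: PAS with the largest usage change between the
      # maximizing switch tissue pair
      ta <- sw_tab$tissue_a[i]
      tb <- sw_tab$tissue_b[i]
      ug <- usage_tissue[usage_tissue$gene_id == g &
                           usage_tissue$tissue %in% c(ta, tb), , drop = FALSE]
      if (!nrow(ug)) next
      ua <- stats::setNames(rep(0, length(unique(ug$pas_id))), unique(ug$pas_id))
      ub <- ua
      sel_a <- ug$tissue == ta
      ua[ug$pas_id[sel_a]] <- ug$usage[sel_a]
      ub[ug$pas_id[!sel_a]] <- ug$usage[!sel_a]
      sec <- names(which.max(abs(ua - ub)))
    }
    out$secondary_pas[i] <- sec
    exp_t <- names(expressed)[vapply(expressed, function(x) g %in% x, TRUE)]
    sec_u <- vapply(exp_t, function(t) {
      m <- match(paste(g, t, sec), u_key)
      if (is.na(m)) 0 else usage_tissue$usage[m]
    }, 0)
    rpm <- tiss_rpm$rpm[match(paste(g, exp_t), r_key)]
    # correlation arm (needs >= 3 expressing tissues)
    if (length(exp_t) >= 3L && stats::sd(sec_u) > 0 && stats::sd(rpm) > 0) {
      ct <- suppressWarnings(stats::cor.test(rpm, sec_u, method = "spearman"))
      if (!is.na(ct$estimate) && ct$estimate > 0 &&
          !is.na(ct$p.value) && ct$p.value < cor_alpha) {
        out$high_confidence[i] <- TRUE
        out$hc_arm[i] <- "correlation"
        next
      }
    }
    # median arm: expression in the tissue of maximal secondary usage
    t_peak <- exp_t[which.max(sec_u)]
    if (!is.na(med_rpm[t_peak]) &&
        isTRUE(rpm[which.max(sec_u)] > med_rpm[t_peak])) {
      out$high_confidence[i] <- TRUE
      out$hc_arm[i] <- "median"
    }
  }
  rownames(out) <- NULL
  out
}

#' Flag genes with brain-specific minor functional PASs
#'
#' TRUE iff the per-tissue F2 criterion holds in at least one brain tissue
#' (cortex and/or cerebellum by default) and in no other tissue.
#'
#' @param groups table from [classify_f1_f2_fu()] (uses `f2_tissues`).
#' @param brain_tissues labels counted as brain (default `c("COR", "CER")`).
#' @return Logical vector named by gene id.
#' @export
flag_brain_specific_f2 <- function(groups, brain_tissues = c("COR", "CER")) {
  res <- vapply(seq_len(nrow(groups)), function(i) {
    ts <- groups$f2_tissues[i]
    if (is.na(ts)) return(FALSE)
    ts <- strsplit(ts, ",", fixed = TRUE)[[1L]]
    any(ts %in% brain_tissues) && all(ts %in% brain_tissues)
  }, TRUE)
  stats::setNames(res, groups$gene_id)
}

#' Full gene classification
#'
#' Orchestrates [classify_f1_f2_fu()], [flag_switched()],
#' [functional_and_high_confidence()] and [flag_brain_specific_f2()] into one
#' per-gene table.
#'
#' @inheritParams functional_and_high_confidence
#' @param dominant,gene_info output of [dominant_and_major_pas()].
#' @param stats output of [diversity_stats()].
#' @param f1_min,f2_gap,switch_threshold,cor_alpha thresholds (see the
#'   stage functions).
#' @param brain_tissues labels counted as brain.
#' @return `data.frame`: one row per multi-PAS gene with `group`, `switched`,
#'   `functional_type`, `secondary_pas`, `high_confidence`, `hc_arm`,
#'   `brain_specific_f2`, plus major-PAS labels merged from `gene_info`.
#' @export
classify_genes <- function(dominant, gene_info, stats, usage_tissue,
                           expression, expressed, f1_min = 0.90,
                           f2_gap = 0.20, switch_threshold = 0.50,
                           cor_alpha = 0.05,
                           brain_tissues = c("COR", "CER")) {
  groups <- classify_f1_f2_fu(dominant, gene_info, f1_min = f1_min,
                              f2_gap = f2_gap)
  switched <- flag_switched(stats$switch, threshold = switch_threshold)
  fun <- functional_and_high_confidence(groups, switched, usage_tissue,
                                        expression, expressed, stats$switch,
                                        cor_alpha = cor_alpha)
  brain <- flag_brain_specific_f2(groups, brain_tissues = brain_tissues)
  out <- merge(groups, fun, by = "gene_id", sort = TRUE)
  out$switched <- switched[out$gene_id] %in% TRUE
  out$brain_specific_f2 <- brain[out$gene_id]
  gi <- gene_info[match(out$gene_id, gene_info$gene_id), , drop = FALSE]
  out$major_pas <- gi$major_pas
  out$major_usage <- gi$major_usage
  out$major_location <- gi$major_location
  rownames(out) <- NULL
  out
}
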