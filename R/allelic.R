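# Allele-specific usage estimation, cis-divergence calling and the allelic
# summary analyses.
#
# Divergence between the parental alleles is tested per PAS with a
# replicate-stratified Cochran-Mantel-Haenszel (CMH) chi-square on
# (this PAS vs rest of gene) x (B6 vs SPR) tables, followed by
# Benjamini-Hochberg adjustment within each tissue; a PAS is divergent iff
# adjusted p < 0.05 and the allelic usage difference exceeds 10%.

#' Allelic usage with coverage and consistency filters
#'
#' Applies, per gene and tissue: (1) exclusion-list removal (imprinted /
#' sex-chromosome / mitochondrial genes); (2) coverage: the gene x tissue is
#' dropped when any sample has fewer than `min_allelic` allele-specific reads
#' for either allele; (3) consistency: a PAS whose usage estimated from
#' allelic reads alone differs by more than `max_inconsistency` from the
#' estimate using allelic + common reads is removed from allelic analyses.
#' Remaining allelic usage is allele-channel reads over the allele-channel
#' gene total (kept PASs only, replicates pooled).
#'
#' @param counts long counts `data.frame` (all three channels).
#' @param exclusion_list gene ids to exclude (may be empty).
#' @param annotations optional annotation table fixing PAS order.
#' @param min_allelic per-sample minimum allele-specific reads per allele
#'   (default 10).
#' @param max_inconsistency allelic-vs-combined usage tolerance
#'   (default 0.10).
#' @return List: `usage` (gene x tissue x allele x PAS allelic usages),
#'   `testable` (gene x tissue passing all filters), `dropped` (gene x
#'   tissue with reason), `removed_pas` (inconsistent PASs with their usage
#'   gap), and `counts_kept` (long counts restricted to testable gene x
#'   tissue and kept PASs; all channels).
#' @export
allelic_usage_with_filters <- function(counts, exclusion_list = character(),
                                       annotations = NULL, min_allelic = 10L,
                                       max_inconsistency = 0.10) {
  validate_counts(counts)
  excl <- counts$gene_id %in% exclusion_list
  dropped <- list()
  if (any(excl)) {
    dropped[["excl"]] <- data.frame(
      gene_id = unique(counts$gene_id[excl]), tissue = NA_character_,
      reason = "exclusion_list", stringsAsFactors = FALSE)
    counts <- counts[!excl, , drop = FALSE]
  }
  cube <- build_cube(counts, annotations)
  tissues <- unique(cube$samples$tissue)
  usage_rows <- list()
  removed_pas <- list()
  testable <- list()
  keep_keys <- character()
  for (g in cube$genes) {
    a <- cube$arrays[[g]]
    for (t in tissues) {
      sc <- tissue_cols(cube, t)
      b6 <- a[, sc, "B6", drop = FALSE][, , 1L, drop = FALSE]
      spr <- a[, sc, "SPR", drop = FALSE][, , 1L, drop = FALSE]
      com <- a[, sc, "common", drop = FALSE][, , 1L, drop = FALSE]
      dim(b6) <- dim(spr) <- dim(com) <- c(dim(a)[1L], length(sc))
      if (any(colSums(b6) < min_allelic) || any(colSums(spr) < min_allelic)) {
        dropped[[paste(g, t)]] <- data.frame(gene_id = g, tissue = t,
                                             reason = "low_allelic_coverage",
                                             stringsAsFactors = FALSE)
        next
      }
      al <- rowSums(b6) + rowSums(spr)
      comb <- al + rowSums(com)
      gap <- abs(al / sum(al) - comb / sum(comb))
      bad <- gap > max_inconsistency
      if (any(bad)) {
        removed_pas[[paste(g, t)]] <- data.frame(
          gene_id = g, tissue = t, pas_id = rownames(a)[bad],
          usage_gap = gap[bad], stringsAsFactors = FALSE)
      }
      keep <- !bad
      if (!any(keep) || sum(rowSums(b6)[keep]) == 0 ||
          sum(rowSums(spr)[keep]) == 0) {
        dropped[[paste(g, t)]] <- data.frame(gene_id = g, tissue = t,
                                             reason = "no_consistent_pas",
                                             stringsAsFactors = FALSE)
        next
      }
      testable[[paste(g, t)]] <- data.frame(gene_id = g, tissue = t,
                                            stringsAsFactors = FALSE)
      keep_keys <- c(keep_keys,
                     paste(g, t, rownames(a)[keep], sep = "\r"))
      ub <- rowSums(b6)[keep] / sum(rowSums(b6)[keep])
      us <- rowSums(spr)[keep] / sum(rowSums(spr)[keep])
      usage_rows[[paste(g, t)]] <- data.frame(
        gene_id = g, tissue = t,
        allele = rep(c("B6", "SPR"), each = sum(keep)),
        pas_id = rep(rownames(a)[keep], 2L), usage = c(ub, us),
        total_reads = rep(c(sum(rowSums(b6)[keep]),
                            sum(rowSums(spr)[keep])), each = sum(keep)),
        stringsAsFactors = FALSE)
    }
  }
  bindr <- function(x, cols) {
    if (length(x)) {
      r <- do.call(rbind, x)
      rownames(r) <- NULL
      return(r)
    }
    as.data.frame(stats::setNames(rep(list(character()), length(cols)), cols),
                  stringsAsFactors = FALSE)
  }
  counts_kept <- counts[paste(counts$gene_id, counts$tissue, counts$pas_id,
                              sep = "\r") %in% keep_keys, , drop = FALSE]
  list(usage = bindr(usage_rows, c("gene_id", "tissue", "allele", "pas_id",
                                   "usage", "total_reads")),
       testable = bindr(testable, c("gene_id", "tissue")),
       dropped = bindr(dropped, c("gene_id", "tissue", "reason")),
       removed_pas = bindr(removed_pas, c("gene_id", "tissue", "pas_id",
                                          "usage_gap")),
       counts_kept = counts_kept)
}

#' Cochran-Mantel-Haenszel chi-square for 2x2xK tables
#'
#' Continuity-corrected CMH statistic combining replicate-stratified 2x2
#' tables; on a single stratum it reduces to the continuity-corrected
#' chi-square test of independence.
#'
#' @param tab integer array 2 x 2 x K (strata in the third dimension).
#' @param correct apply the 0.5 continuity correction (default TRUE).
#' @return List with `statistic`, `p.value`, and `degenerate` (TRUE when
#'   every stratum has a zero margin, in which case p = 1).
#' @export
cmh_test <- function(tab, correct = TRUE) {
  if (length(dim(tab)) == 2L) tab <- array(tab, dim = c(dim(tab), 1L))
  K <- dim(tab)[3L]
  num <- 0
  den <- 0
  for (k in seq_len(K)) {
    m <- tab[, , k]
    n <- sum(m)
    if (n == 0) next
    r1 <- sum(m[1L, ])
    r2 <- sum(m[2L, ])
    c1 <- sum(m[, 1L])
    c2 <- sum(m[, 2L])
    if (n <= 1 || r1 * r2 * c1 * c2 == 0) next
    num <- num + (m[1L, 1L] - r1 * c1 / n)
    den <- den + r1 * r2 * c1 * c2 / (n^2 * (n - 1))
  }
  if (den == 0) {
    return(list(statistic = NA_real_, p.value = 1, degenerate = TRUE))
  }
  # Yates correction only when it cannot overshoot (|num| >= 0.5), the
  # standard convention
  yates <- if (correct && abs(num) >= 0.5) 0.5 else 0
  stat <- (abs(num) - yates)^2 / den
  list(statistic = stat,
       p.value = stats::pchisq(stat, df = 1L, lower.tail = FALSE),
       degenerate = FALSE)
}

#' Call allelic PAS usage divergence
#'
#' Per testable gene x tissue and PAS, builds replicate-stratified 2x2
#' tables of (this PAS vs rest of gene) x (B6 vs SPR) allele-specific reads,
#' combines them with [cmh_test()], adjusts p-values per tissue with
#' Benjamini-Hochberg over all tested PASs, and flags a PAS divergent iff
#' adjusted p < `alpha` and |usage_B6 - usage_SPR| > `min_delta`. A gene is
#' divergent in a tissue iff its dominant PAS there (highest all-channel
#' pooled usage among kept PASs) is divergent.
#'
#' @param filtered result of [allelic_usage_with_filters()].
#' @param alpha BH-adjusted p-value threshold (default 0.05).
#' @param min_delta allelic usage-difference threshold (default 0.10,
#'   exclusive).
#' @param correct continuity correction for the CMH statistic.
#' @return List: `calls` (per PAS x tissue: `usage_B6`, `usage_SPR`, `delta`
#'   = B6 - SPR, `p_raw`, `p_adj`, `divergent`, `degenerate`) and `genes`
#'   (per gene x tissue: `dominant_pas`, `divergent`).
#' @export
call_divergence <- function(filtered, alpha = 0.05, min_delta = 0.10,
                            correct = TRUE) {
  cc <- filtered$counts_kept
  if (!nrow(filtered$testable)) {
    stop("no testable gene x tissue after filtering")
  }
  cube <- build_cube(cc)
  u_key <- paste(filtered$usage$gene_id, filtered$usage$tissue,
                 filtered$usage$allele, filtered$usage$pas_id)
  u_val <- filtered$usage$usage
  o_gene <- o_tissue <- o_pas <- character()
  o_ub <- o_us <- o_p <- numeric()
  o_deg <- o_dom <- logical()
  for (i in seq_len(nrow(filtered$testable))) {
    g <- filtered$testable$gene_id[i]
    t <- filtered$testable$tissue[i]
    a <- cube$arrays[[g]]
    sc <- tissue_cols(cube, t)
    b6 <- matrix(a[, sc, "B6"], nrow = dim(a)[1L])
    spr <- matrix(a[, sc, "SPR"], nrow = dim(a)[1L])
    tot <- matrix(cube_total(a)[, sc], nrow = dim(a)[1L])
    pas <- rownames(a)
    ub <- u_val[match(paste(g, t, "B6", pas), u_key)]
    us <- u_val[match(paste(g, t, "SPR", pas), u_key)]
    # PASs without allelic usage in this tissue (consistency-removed) are
    # not tested here; their zero rows do not enter the 2x2 tables either
    sel <- !is.na(ub)
    pas <- pas[sel]
    ub <- ub[sel]
    us <- us[sel]
    b6 <- b6[sel, , drop = FALSE]
    spr <- spr[sel, , drop = FALSE]
    tot <- tot[sel, , drop = FALSE]
    k <- length(pas)
    dom <- pas[order(-rowSums(tot), pas)][1L]
    p <- rep(1, k)
    deg <- rep(TRUE, k)
    if (k > 1L) {
      cs_b <- colSums(b6)
      cs_s <- colSums(spr)
      for (j in seq_len(k)) {
        tabs <- array(0, dim = c(2L, 2L, length(sc)))
        tabs[1L, 1L, ] <- b6[j, ]
        tabs[2L, 1L, ] <- cs_b - b6[j, ]
        tabs[1L, 2L, ] <- spr[j, ]
        tabs[2L, 2L, ] <- cs_s - spr[j, ]
        ct <- cmh_test(tabs, correct = correct)
        p[j] <- ct$p.value
        deg[j] <- ct$degenerate
      }
    }
    o_gene <- c(o_gene, rep(g, k))
    o_tissue <- c(o_tissue, rep(t, k))
    o_pas <- c(o_pas, pas)
    o_ub <- c(o_ub, ub)
    o_us <- c(o_us, us)
    o_p <- c(o_p, p)
    o_deg <- c(o_deg, deg)
    o_dom <- c(o_dom, pas == dom)
  }
  calls <- data.frame(gene_id = o_gene, tissue = o_tissue, pas_id = o_pas,
                      usage_B6 = o_ub, usage_SPR = o_us,
                      delta = ifelse(is.na(o_ub) | is.na(o_us), NA_real_,
                                     o_ub - o_us),
                      p_raw = o_p, degenerate = o_deg, is_dominant = o_dom,
                      stringsAsFactors = FALSE)
  calls$p_adj <- NA_real_
  for (t in unique(calls$tissue)) {
    sel <- calls$tissue == t
    calls$p_adj[sel] <- stats::p.adjust(calls$p_raw[sel], method = "BH")
  }
  calls$divergent <- calls$p_adj < alpha & abs(calls$delta) > min_delta
  gd <- calls[calls$is_dominant, , drop = FALSE]
  genes <- data.frame(gene_id = gd$gene_id, tissue = gd$tissue,
                      dominant_pas = gd$pas_id, divergent = gd$divergent,
                      stringsAsFactors = FALSE)
  rownames(genes) <- NULL
  list(calls = calls, genes = genes)
}

#' Classify genes by divergence across tissues
#'
#' @param gene_calls `genes` table from [call_divergence()].
#' @return `data.frame` per gene: `n_testable_tissues`, `n_divergent`, and
#'   `class` in non_divergent / some_divergent / all_divergent.
#' @export
classify_divergence <- function(gene_calls) {
  n_test <- table(gene_calls$gene_id)
  n_div <- tapply(gene_calls$divergent, gene_calls$gene_id, sum)
  g <- names(n_test)
  nd <- as.vector(n_div[g])
  nt <- as.vector(n_test[g])
  cls <- ifelse(nd == 0, "non_divergent",
                ifelse(nd == nt, "all_divergent", "some_divergent"))
  data.frame(gene_id = g, n_testable_tissues = nt, n_divergent = nd,
             class = cls, stringsAsFactors = FALSE, row.names = NULL)
}

#' Scaling of allelic usage difference with major-PAS usage
#'
#' Bins genes by the B6-allele usage of their major PAS and summarizes the
#' |delta| distribution per bin, with Mann-Whitney tests between adjacent
#' bins.
#'
#' @param deltas `data.frame` with columns `usage_b6` (B6-allele major-PAS
#'   usage) and `delta` (allelic usage difference of that PAS).
#' @param bins ascending break points (default `seq(0.5, 1, 0.1)`; the last
#'   bin is closed).
#' @return List: `table` (per bin: `n`, `median_abs_delta`, `mean_abs_delta`)
#'   and `tests` (adjacent-bin Mann-Whitney p-values; empty when fewer than
#'   two bins are occupied).
#' @export
scaling_law_table <- function(deltas, bins = seq(0.5, 1, 0.1)) {
  if (!nrow(deltas)) {
    return(list(table = data.frame(bin = character(), n = integer(),
                                   median_abs_delta = numeric(),
                                   mean_abs_delta = numeric()),
                tests = data.frame(bin_a = character(), bin_b = character(),
                                   p = numeric())))
  }
  # [a, b) bins, the last one closed at the top
  cut_bin <- cut(deltas$usage_b6, breaks = bins, include.lowest = TRUE,
                 right = FALSE)
  ad <- abs(deltas$delta)
  keep <- !is.na(cut_bin)
  tab <- data.frame(
    bin = levels(cut_bin),
    n = as.vector(table(cut_bin[keep])),
    median_abs_delta = as.vector(tapply(ad[keep], cut_bin[keep], stats::median)),
    mean_abs_delta = as.vector(tapply(ad[keep], cut_bin[keep], mean)),
    stringsAsFactors = FALSE)
  occ <- which(tab$n > 0)
  tests <- list()
  if (length(occ) >= 2L) {
    for (i in seq_len(length(occ) - 1L)) {
      a <- tab$bin[occ[i]]
      b <- tab$bin[occ[i + 1L]]
      p <- suppressWarnings(stats::wilcox.test(
        ad[keep][cut_bin[keep] == a], ad[keep][cut_bin[keep] == b]))$p.value
      tests[[i]] <- data.frame(bin_a = a, bin_b = b, p = p,
                               stringsAsFactors = FALSE)
    }
  }
  list(table = tab,
       tests = if (length(tests)) do.call(rbind, tests) else
         data.frame(bin_a = character(), bin_b = character(), p = numeric()))
}

#' Allelic sequence-variant density around PASs
#'
#' Counts variants in the strand-oriented window (`window[1]`, `window[2]`)
#' around each cleavage position (negative = transcriptionally upstream;
#' both ends inclusive) and divides by the window length. Also returns the
#' aggregated per-offset variant profile.
#'
#' @param variants `data.frame` with columns `chrom` and `pos` (0-based
#'   variant positions).
#' @param annotations PAS annotation `data.frame`.
#' @param window integer window relative to the cleavage site
#'   (default `c(-200, 100)`).
#' @return List: `density` (per PAS: `n_variants`, `density`) and `profile`
#'   (per offset: total variant count over all PASs).
#' @export
variant_density <- function(variants, annotations, window = c(-200L, 100L)) {
  validate_annotations(annotations)
  len <- window[2L] - window[1L] + 1L
  n_var <- integer(nrow(annotations))
  profile <- stats::setNames(integer(len), seq(window[1L], window[2L]))
  for (i in seq_len(nrow(annotations))) {
    v <- variants$pos[variants$chrom == annotations$chrom[i]]
    if (!length(v)) next
    off <- if (annotations$strand[i] == "+") {
      v - annotations$cleavage_pos[i]
    } else {
      annotations$cleavage_pos[i] - v
    }
    inside <- off >= window[1L] & off <= window[2L]
    n_var[i] <- sum(inside)
    if (any(inside)) {
      tb <- table(off[inside])
      profile[names(tb)] <- profile[names(tb)] + as.integer(tb)
    }
  }
  list(density = data.frame(gene_id = annotations$gene_id,
                            pas_id = annotations$pas_id, n_variants = n_var,
                            density = n_var / len, stringsAsFactors = FALSE),
       profile = data.frame(offset = as.integer(names(profile)),
                            n_variants = as.integer(profile),
                            stringsAsFactors = FALSE))
}

#' Hierarchical clustering of allelic APA and expression patterns
#'
#' Restricts to genes testable in every tissue. The APA feature per gene is
#' the allelic usage of its maximum-average-usage PAS across the
#' tissue x allele samples; the expression feature is allelic log2 RPM.
#' Samples are clustered with average linkage on 1 - Pearson correlation.
#'
#' @param filtered result of [allelic_usage_with_filters()].
#' @param expression result of [compute_expression()] (for `allelic_rpm`);
#'   may be `NULL` to skip expression clustering.
#' @param tissues tissue labels that must all be testable.
#' @return List: `usage` and (if requested) `expression`, each with
#'   `features` (gene x sample matrix), `cor` (sample correlation matrix),
#'   `hclust`, and `newick`; plus `genes` (the gene set used).
#' @export
allelic_clustering <- function(filtered, expression = NULL, tissues) {
  u <- filtered$usage[filtered$usage$tissue %in% tissues, , drop = FALSE]
  # candidate PASs must carry allelic usage in every tissue x allele cell
  gp <- paste(u$gene_id, u$pas_id, sep = "\r")
  cells <- table(gp)
  eligible <- names(cells)[cells == 2L * length(tissues)]
  if (length(eligible) < 2L) {
    stop("need at least two genes with a PAS measurable in all tissues")
  }
  keep_pas <- gp %in% eligible
  avg <- tapply(u$usage[keep_pas], gp[keep_pas], mean)
  parts <- do.call(rbind, strsplit(names(avg), "\r", fixed = TRUE))
  best <- vapply(split(seq_along(avg), parts[, 1L]), function(ix) {
    ix[order(-avg[ix], parts[ix, 2L])][1L]
  }, 0L)
  feat_pas <- stats::setNames(parts[best, 2L], names(best))
  genes <- names(feat_pas)
  if (length(genes) < 2L) {
    stop("need at least two genes with a PAS measurable in all tissues")
  }
  u <- u[u$gene_id %in% genes, , drop = FALSE]
  cols <- as.vector(outer(tissues, c("B6", "SPR"), paste, sep = "_"))
  mat <- matrix(NA_real_, nrow = length(genes), ncol = length(cols),
                dimnames = list(genes, cols))
  sel <- u$pas_id == feat_pas[u$gene_id]
  us <- u[sel, , drop = FALSE]
  mat[cbind(us$gene_id, paste(us$tissue, us$allele, sep = "_"))] <- us$usage
  cluster_block <- function(m) {
    cm <- stats::cor(m, use = "pairwise.complete.obs")
    hc <- stats::hclust(stats::as.dist(1 - cm), method = "average")
    list(features = m, cor = cm, hclust = hc,
         newick = ape::write.tree(ape::as.phylo(hc)))
  }
  out <- list(genes = genes, usage = cluster_block(mat))
  if (!is.null(expression)) {
    ar <- expression$allelic_rpm
    samp_t <- sub("_r[0-9]+$", "", ar$sample)
    key <- paste(ar$gene_id, samp_t, ar$allele, sep = "\r")
    mean_rpm <- tapply(ar$rpm, key, mean)
    kp <- do.call(rbind, strsplit(names(mean_rpm), "\r", fixed = TRUE))
    keep <- kp[, 1L] %in% genes & kp[, 2L] %in% tissues
    em <- matrix(NA_real_, nrow = length(genes), ncol = length(cols),
                 dimnames = list(genes, cols))
    em[cbind(kp[keep, 1L], paste(kp[keep, 2L], kp[keep, 3L], sep = "_"))] <-
      log2(mean_rpm[keep] + 1)
    out$expression <- cluster_block(em)
  }
  out
}

#' Allelic gene-expression divergence
#'
#' Per gene and tissue, compares total B6 vs SPR allele-specific reads: each
#' replicate contributes a normal-approximation binomial z-score against a
#' 1/2 allelic split; replicates combine by Stouffer's method; p-values are
#' BH-adjusted per tissue. Divergent iff the pooled allelic fold change
#' exceeds `fc_threshold` (either direction) and adjusted p < `alpha`.
#'
#' @param counts long counts `data.frame`.
#' @param fc_threshold fold-change threshold (default 2).
#' @param alpha adjusted-p threshold (default 0.05).
#' @return `data.frame` per gene x tissue with `b6_reads`, `spr_reads`,
#'   `log2_fold`, `p_raw`, `p_adj`, `divergent`.
#' @export
allelic_expression_divergence <- function(counts, fc_threshold = 2,
                                          alpha = 0.05) {
  validate_counts(counts)
  al <- counts[counts$channel %in% c("B6", "SPR"), , drop = FALSE]
  key <- paste(al$gene_id, al$tissue, al$sample, al$channel, sep = "\r")
  tot <- rowsum(al$count, key)
  parts <- do.call(rbind, strsplit(rownames(tot), "\r", fixed = TRUE))
  df <- data.frame(gene_id = parts[, 1L], tissue = parts[, 2L],
                   sample = parts[, 3L], channel = parts[, 4L],
                   reads = tot[, 1L], stringsAsFactors = FALSE)
  rows <- list()
  for (chunk in split(df, paste(df$gene_id, df$tissue, sep = "\r"))) {
    g <- chunk$gene_id[1L]
    t <- chunk$tissue[1L]
    z <- c()
    b6_tot <- spr_tot <- 0
    for (s in unique(chunk$sample)) {
      b6 <- sum(chunk$reads[chunk$sample == s & chunk$channel == "B6"])
      spr <- sum(chunk$reads[chunk$sample == s & chunk$channel == "SPR"])
      n <- b6 + spr
      b6_tot <- b6_tot + b6
      spr_tot <- spr_tot + spr
      if (n > 0) z <- c(z, (b6 - n / 2) / sqrt(n / 4))
    }
    if (!length(z)) next
    zc <- sum(z) / sqrt(length(z))
    p <- 2 * stats::pnorm(-abs(zc))
    rows[[paste(g, t)]] <- data.frame(
      gene_id = g, tissue = t, b6_reads = b6_tot, spr_reads = spr_tot,
      log2_fold = log2((b6_tot + 0.5) / (spr_tot + 0.5)), p_raw = p,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$p_adj <- NA_real_
  for (t in unique(out$tissue)) {
    sel <- out$tissue == t
    out$p_adj[sel] <- stats::p.adjust(out$p_raw[sel], method = "BH")
  }
  out$divergent <- abs(out$log2_fold) > log2(fc_threshold) & out$p_adj < alpha
  out
}
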