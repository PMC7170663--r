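# Expression and PAS-usage quantification with the coverage filters, the
# dominant/major PAS labels, and the equal-depth down-sampled dataset.

#' Per-tissue expressed-gene sets
#'
#' A gene is expressed in a tissue iff its total PAS reads (all channels
#' summed) reach `min_reads` in EVERY replicate of that tissue.
#'
#' @param counts long counts `data.frame`.
#' @param min_reads minimum PAS reads per replicate (default 20).
#' @return Named list (one element per tissue) of expressed gene-id vectors.
#' @export
filter_expressed_genes <- function(counts, min_reads = 20L) {
  validate_counts(counts)
  tissues <- sort(unique(counts$tissue))
  tot <- rowsum(counts$count,
                paste(counts$tissue, counts$sample, counts$gene_id, sep = "\r"))
  parts <- do.call(rbind, strsplit(rownames(tot), "\r", fixed = TRUE))
  df <- data.frame(tissue = parts[, 1L], sample = parts[, 2L],
                   gene_id = parts[, 3L], total = tot[, 1L],
                   stringsAsFactors = FALSE)
  samp <- unique(counts[, c("sample", "tissue")])
  n_rep <- table(samp$tissue)
  out <- vector("list", length(tissues))
  names(out) <- tissues
  for (t in tissues) {
    if (n_rep[[t]] < 1L) stop("tissue without replicates: ", t)
    d <- df[df$tissue == t, , drop = FALSE]
    ok <- tapply(d$total >= min_reads, d$gene_id,
                 function(x) all(x) && length(x) == n_rep[[t]])
    out[[t]] <- sort(names(ok)[ok])
  }
  out
}

#' Used-PAS sets
#'
#' A PAS counts as used iff it gathered at least `min_reads` reads (all
#' channels) in at least one sample of any tissue. Unused PASs are removed
#' before usage computation and their reads excluded from denominators.
#'
#' @param counts long counts `data.frame`.
#' @param min_reads minimum reads in a single sample (default 5).
#' @return `data.frame` with columns `gene_id`, `pas_id` of used PASs.
#' @export
filter_used_pas <- function(counts, min_reads = 5L) {
  validate_counts(counts)
  tot <- rowsum(counts$count,
                paste(counts$gene_id, counts$pas_id, counts$sample, sep = "\r"))
  keep <- rownames(tot)[tot[, 1L] >= min_reads]
  parts <- unique(do.call(rbind,
                          strsplit(keep, "\r", fixed = TRUE))[, 1:2, drop = FALSE])
  used <- data.frame(gene_id = parts[, 1L], pas_id = parts[, 2L],
                     stringsAsFactors = FALSE)
  used[order(used$gene_id, used$pas_id), , drop = FALSE]
}

# restrict counts to used PASs
restrict_to_used <- function(counts, used) {
  counts[paste(counts$gene_id, counts$pas_id) %in%
           paste(used$gene_id, used$pas_id), , drop = FALSE]
}

#' Relative PAS usage
#'
#' Usage of a PAS is its read count divided by the gene's summed PAS reads at
#' the requested scope. `tissue` scope pools replicate counts before
#' normalizing; `tissue_allele` uses only the B6 or SPR channel. Gene/scope
#' cells with a zero denominator yield no usage rows (flagged missing rather
#' than NaN).
#'
#' @param counts long counts `data.frame`.
#' @param used used-PAS table from [filter_used_pas()]; usage is computed
#'   over these PASs only.
#' @param scope one of "sample", "tissue", "tissue_allele".
#' @return `data.frame` with columns `gene_id`, scope keys (`sample` or
#'   `tissue`, plus `allele` for `tissue_allele`), `pas_id`, `usage`,
#'   `total_reads`.
#' @export
compute_usage <- function(counts, used,
                          scope = c("tissue", "sample", "tissue_allele")) {
  scope <- match.arg(scope)
  validate_counts(counts)
  cc <- restrict_to_used(counts, used)
  if (scope == "tissue_allele") {
    cc <- cc[cc$channel %in% c("B6", "SPR"), , drop = FALSE]
    unit <- paste(cc$tissue, cc$channel, sep = "\r")
  } else if (scope == "tissue") {
    unit <- cc$tissue
  } else {
    unit <- cc$sample
  }
  key <- paste(cc$gene_id, unit, cc$pas_id, sep = "\r\r")
  pas_tot <- rowsum(cc$count, key)
  parts <- do.call(rbind, strsplit(rownames(pas_tot), "\r\r", fixed = TRUE))
  gk <- paste(parts[, 1L], parts[, 2L], sep = "\r\r")
  gene_tot <- rowsum(pas_tot[, 1L], gk)
  denom <- gene_tot[match(gk, rownames(gene_tot)), 1L]
  keep <- denom > 0
  out <- data.frame(gene_id = parts[keep, 1L], stringsAsFactors = FALSE)
  if (scope == "tissue_allele") {
    ta <- do.call(rbind, strsplit(parts[keep, 2L], "\r", fixed = TRUE))
    out$tissue <- ta[, 1L]
    out$allele <- ta[, 2L]
  } else if (scope == "tissue") {
    out$tissue <- parts[keep, 2L]
  } else {
    out$sample <- parts[keep, 2L]
  }
  out$pas_id <- parts[keep, 3L]
  out$usage <- pas_tot[keep, 1L] / denom[keep]
  out$total_reads <- denom[keep]
  rownames(out) <- NULL
  out[do.call(order, out[seq_len(ncol(out) - 2L)]), , drop = FALSE]
}

#' Gene expression as reads per million (RPM)
#'
#' RPM = 1e6 x gene PAS reads / total PAS reads in the sample. Allelic RPM
#' uses the gene's allele-channel reads over the same total-sample
#' denominator.
#'
#' @param counts long counts `data.frame` (all channels).
#' @return List with `sample_rpm` (gene x sample), `tissue_rpm` (gene x
#'   tissue mean over replicates), `allelic_rpm` (gene x sample x allele),
#'   and `sample_totals`.
#' @export
compute_expression <- function(counts) {
  validate_counts(counts)
  sample_totals <- rowsum(counts$count, counts$sample)
  gk <- paste(counts$gene_id, counts$sample, sep = "\r")
  gene_tot <- rowsum(counts$count, gk)
  parts <- do.call(rbind, strsplit(rownames(gene_tot), "\r", fixed = TRUE))
  sample_rpm <- data.frame(gene_id = parts[, 1L], sample = parts[, 2L],
                           rpm = 1e6 * gene_tot[, 1L] /
                             sample_totals[match(parts[, 2L],
                                                 rownames(sample_totals)), 1L],
                           stringsAsFactors = FALSE)
  samp <- unique(counts[, c("sample", "tissue")])
  sample_rpm$tissue <- samp$tissue[match(sample_rpm$sample, samp$sample)]
  tk <- paste(sample_rpm$gene_id, sample_rpm$tissue, sep = "\r")
  n_rep <- table(samp$tissue)
  mean_rpm <- rowsum(sample_rpm$rpm, tk)
  tparts <- do.call(rbind, strsplit(rownames(mean_rpm), "\r", fixed = TRUE))
  # divide by the tissue's replicate count so absent samples count as zero
  tissue_rpm <- data.frame(gene_id = tparts[, 1L], tissue = tparts[, 2L],
                           rpm = mean_rpm[, 1L] /
                             as.vector(n_rep[tparts[, 2L]]),
                           stringsAsFactors = FALSE)
  al <- counts[counts$channel %in% c("B6", "SPR"), , drop = FALSE]
  ak <- paste(al$gene_id, al$sample, al$channel, sep = "\r")
  a_tot <- rowsum(al$count, ak)
  aparts <- do.call(rbind, strsplit(rownames(a_tot), "\r", fixed = TRUE))
  allelic_rpm <- data.frame(gene_id = aparts[, 1L], sample = aparts[, 2L],
                            allele = aparts[, 3L],
                            rpm = 1e6 * a_tot[, 1L] /
                              sample_totals[match(aparts[, 2L],
                                                  rownames(sample_totals)), 1L],
                            stringsAsFactors = FALSE)
  list(sample_rpm = sample_rpm[order(sample_rpm$gene_id, sample_rpm$sample), ],
       tissue_rpm = tissue_rpm[order(tissue_rpm$gene_id, tissue_rpm$tissue), ],
       allelic_rpm = allelic_rpm,
       sample_totals = data.frame(sample = rownames(sample_totals),
                                  total = sample_totals[, 1L],
                                  stringsAsFactors = FALSE, row.names = NULL))
}

#' Dominant and major PAS labels
#'
#' The dominant PAS is the highest-usage PAS of a gene in one expressing
#' tissue; the major PAS maximizes the unweighted mean usage across all
#' expressing tissues. Ties break to the smaller cleavage coordinate. A gene
#' is single-PAS iff exactly one used PAS serves it in all tissues. The major
#' PAS's location class is `upstream`, or `utr3_S`/`utr3_F`/`utr3_M`/`utr3_L`
#' for the sole / most proximal / middle / most distal PAS in the 3'UTR,
#' computed over the gene's used 3'UTR PASs.
#'
#' @param usage_tissue tissue-scope usage from [compute_usage()].
#' @param expressed per-tissue expressed-gene sets from
#'   [filter_expressed_genes()].
#' @param annotations annotation `data.frame` (coordinates for tie-breaks and
#'   location classes).
#' @return List with `dominant` (gene x expressing tissue: dominant PAS and
#'   its usage, rank-2 PAS and usage) and `genes` (per-gene: `pas_class`
#'   single/multi, `major_pas`, `major_usage`, `major_location`,
#'   `n_used_pas`, `n_expressing_tissues`).
#' @export
dominant_and_major_pas <- function(usage_tissue, expressed, annotations) {
  validate_annotations(annotations)
  akey <- paste(annotations$gene_id, annotations$pas_id)
  coord <- annotations$cleavage_pos[match(paste(usage_tissue$gene_id,
                                                usage_tissue$pas_id), akey)]
  u <- usage_tissue
  u$coord <- coord
  # keep expressing tissues only
  exp_key <- unlist(lapply(names(expressed), function(t) {
    paste(expressed[[t]], t, sep = "\r")
  }), use.names = FALSE)
  u <- u[paste(u$gene_id, u$tissue, sep = "\r") %in% exp_key, , drop = FALSE]
  if (!nrow(u)) stop("no gene is expressed in any tissue")

  dom_rows <- list()
  gene_rows <- list()
  for (chunk in split(u, u$gene_id)) {
    g <- chunk$gene_id[1L]
    by_t <- split(chunk, chunk$tissue)
    dom <- lapply(by_t, function(d) {
      o <- order(-d$usage, d$coord)
      data.frame(gene_id = g, tissue = d$tissue[1L],
                 dominant_pas = d$pas_id[o[1L]],
                 dominant_usage = d$usage[o[1L]],
                 rank2_pas = if (nrow(d) > 1L) d$pas_id[o[2L]] else NA_character_,
                 rank2_usage = if (nrow(d) > 1L) d$usage[o[2L]] else NA_real_,
                 stringsAsFactors = FALSE)
    })
    dom_rows[[g]] <- do.call(rbind, dom)
    # unweighted mean usage over expressing tissues (absent = usage 0)
    n_t <- length(by_t)
    mean_u <- rowsum(chunk$usage, chunk$pas_id) / n_t
    pas_coord <- chunk$coord[match(rownames(mean_u), chunk$pas_id)]
    o <- order(-mean_u[, 1L], pas_coord)
    major <- rownames(mean_u)[o[1L]]
    used_pas <- rownames(mean_u)
    gene_rows[[g]] <- data.frame(
      gene_id = g,
      pas_class = if (length(used_pas) == 1L) "single" else "multi",
      major_pas = major, major_usage = mean_u[o[1L], 1L],
      major_location = pas_location_class(g, major, used_pas, annotations),
      n_used_pas = length(used_pas), n_expressing_tissues = n_t,
      stringsAsFactors = FALSE)
  }
  dominant <- do.call(rbind, dom_rows)
  rownames(dominant) <- NULL
  genes <- do.call(rbind, gene_rows)
  rownames(genes) <- NULL
  list(dominant = dominant, genes = genes)
}

# Location class of one PAS among a gene's used PASs: upstream, or position
# within the used 3'UTR PASs (S sole, F first/proximal, L last/distal,
# M middle).
pas_location_class <- function(gene_id, pas_id, used_pas, annotations) {
  a <- annotations[annotations$gene_id == gene_id &
                     annotations$pas_id %in% used_pas, , drop = FALSE]
  row <- a[a$pas_id == pas_id, , drop = FALSE]
  if (!nrow(row)) return(NA_character_)
  if (row$region_class == "upstream") return("upstream")
  utr <- a[a$region_class == "utr3", , drop = FALSE]
  m <- nrow(utr)
  if (m == 1L) return("utr3_S")
  o <- if (row$strand == "+") order(utr$cleavage_pos) else order(-utr$cleavage_pos)
  r <- which(utr$pas_id[o] == pas_id)
  if (r == 1L) "utr3_F" else if (r == m) "utr3_L" else "utr3_M"
}

#' Genes with exactly three 3'UTR PASs
#'
#' Selected iff the gene has exactly three used PASs located in the 3'UTR and
#' the sum of their usages is strictly above 0.5 in every tissue where the
#' gene is expressed.
#'
#' @param usage_tissue tissue-scope usage from [compute_usage()].
#' @param annotations annotation `data.frame`.
#' @param expressed per-tissue expressed-gene sets.
#' @return Character vector of gene ids.
#' @export
select_exactly_three_utr_pas_genes <- function(usage_tissue, annotations,
                                               expressed) {
  validate_annotations(annotations)
  akey <- paste(annotations$gene_id, annotations$pas_id)
  is_utr <- annotations$region_class[match(paste(usage_tissue$gene_id,
                                                 usage_tissue$pas_id),
                                           akey)] == "utr3"
  exp_key <- unlist(lapply(names(expressed), function(t) {
    paste(expressed[[t]], t, sep = "\r")
  }), use.names = FALSE)
  u <- usage_tissue[paste(usage_tissue$gene_id, usage_tissue$tissue,
                          sep = "\r") %in% exp_key, , drop = FALSE]
  is_utr <- is_utr[paste(usage_tissue$gene_id, usage_tissue$tissue,
                         sep = "\r") %in% exp_key]
  out <- character()
  for (chunk in split(cbind(u, is_utr = is_utr), u$gene_id)) {
    n_utr <- length(unique(chunk$pas_id[chunk$is_utr]))
    if (n_utr != 3L) next
    sums <- tapply(chunk$usage * chunk$is_utr, chunk$tissue, sum)
    if (all(sums > 0.5)) out <- c(out, chunk$gene_id[1L])
  }
  sort(out)
}

#' Equal-depth down-sampled per-gene PAS counts
#'
#' Each sample's counts are first rescaled to the smallest sample total
#' (stochastic rounding), pooled across samples per gene, and `n` reads are
#' drawn without replacement (multivariate hypergeometric over PAS labels).
#' Genes whose pooled total falls below `n` are skipped and reported.
#'
#' @param counts long counts `data.frame`.
#' @param n reads drawn per gene (default 100).
#' @param seed integer seed.
#' @return `data.frame` with `gene_id`, `pas_id`, `count`; skipped genes in
#'   `attr(, "skipped")`.
#' @export
downsample_counts <- function(counts, n = 100L, seed = 1L) {
  if (n <= 0L) stop("n must be positive")
  validate_counts(counts)
  set.seed(fan_seed(seed, "downsample"))
  sample_totals <- rowsum(counts$count, counts$sample)
  depth <- min(sample_totals[, 1L])
  scale <- depth / sample_totals[match(counts$sample, rownames(sample_totals)), 1L]
  scaled <- stochastic_round(counts$count * scale)
  pooled <- rowsum(scaled, paste(counts$gene_id, counts$pas_id, sep = "\r"))
  parts <- do.call(rbind, strsplit(rownames(pooled), "\r", fixed = TRUE))
  df <- data.frame(gene_id = parts[, 1L], pas_id = parts[, 2L],
                   count = pooled[, 1L], stringsAsFactors = FALSE)
  out <- list()
  skipped <- character()
  for (chunk in split(df, df$gene_id)) {
    tot <- sum(chunk$count)
    if (tot < n) {
      skipped <- c(skipped, chunk$gene_id[1L])
      next
    }
    draw <- rmvhyper(1L, chunk$count, n)[, 1L]
    out[[chunk$gene_id[1L]]] <- data.frame(gene_id = chunk$gene_id[1L],
                                           pas_id = chunk$pas_id,
                                           count = draw,
                                           stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(gene_id = character(), pas_id = character(),
               count = integer(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "skipped") <- skipped
  res
}
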