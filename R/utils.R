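# Internal helpers shared across modules.

CHANNELS <- c("B6", "SPR", "common")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a stage-specific random seed from one pipeline seed
#'
#' A counter-based fan-out: each randomized stage owns a fixed integer tag, so
#' the seed consumed by one stage never depends on whether (or how often) an
#' earlier stage drew random numbers.
#'
#' @param seed master integer seed.
#' @param tag stage tag (integer counter, or a stage name hashed internally).
#' @param i optional sub-counter (e.g. gene index) for per-unit streams.
#' @return An integer seed in [0, 2^31 - 2].
#' @export
fan_seed <- function(seed, tag, i = 0L) {
  if (is.character(tag)) {
    tag <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  }
  m <- 2147483647 # 2^31 - 1, Mersenne prime; keeps results in integer range
  s <- (as.numeric(seed) %% m)
  s <- (s * 48271 + as.numeric(tag) * 1000003 + as.numeric(i) * 7919) %% m
  as.integer(s)
}

# Multivariate hypergeometric draws: sample `n_draw` items without replacement
# from a pool with `pool` items per category; `nn` independent draws.
# Returns a length(pool) x nn integer matrix. Vectorized over draws via
# sequential conditional rhyper calls (one per category).
rmvhyper <- function(nn, pool, n_draw) {
  k <- length(pool)
  out <- matrix(0L, nrow = k, ncol = nn)
  left <- rep.int(as.integer(n_draw), nn)
  tot <- sum(pool)
  for (i in seq_len(k)) {
    tot <- tot - pool[i]
    x <- stats::rhyper(nn, m = pool[i], n = tot, k = left)
    out[i, ] <- x
    left <- left - x
  }
  out
}

# Partition a pooled count vector into G groups with fixed per-group totals,
# uniformly over all assignments of the pooled (labelled) reads; equivalent to
# shuffling read labels without materializing reads. Returns a
# k x G x n_mock integer array whose group margins equal `group_totals`.
partition_counts <- function(pool, group_totals, n_mock = 1L) {
  k <- length(pool)
  G <- length(group_totals)
  stopifnot(sum(pool) == sum(group_totals))
  res <- array(0L, dim = c(k, G, n_mock))
  remaining <- matrix(as.integer(pool), nrow = k, ncol = n_mock)
  for (g in seq_len(G - 1L)) {
    left <- rep.int(as.integer(group_totals[g]), n_mock)
    tot_left <- colSums(remaining)
    for (i in seq_len(k)) {
      m <- remaining[i, ]
      tot_left <- tot_left - m
      x <- stats::rhyper(n_mock, m = m, n = tot_left, k = left)
      res[i, g, ] <- x
      left <- left - x
      remaining[i, ] <- m - x
    }
  }
  res[, G, ] <- remaining
  res
}

# Stochastic rounding: floor(x) + Bernoulli(frac(x)). Unbiased for non-integer
# scaled counts.
stochastic_round <- function(x) {
  f <- floor(x)
  as.integer(f + (stats::runif(length(x)) < (x - f)))
}

# ---- input validation ------------------------------------------------------

validate_annotations <- function(annotations) {
  req <- c("gene_id", "pas_id", "chrom", "strand", "cleavage_pos",
           "region_class", "utr_rank")
  miss <- setdiff(req, names(annotations))
  if (length(miss)) {
    stop("annotation table is missing columns: ", paste(miss, collapse = ", "))
  }
  if (!all(annotations$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'")
  }
  if (!all(annotations$region_class %in% c("upstream", "utr3"))) {
    stop("region_class must be 'upstream' or 'utr3'")
  }
  key <- paste(annotations$gene_id, annotations$pas_id)
  if (anyDuplicated(key)) {
    stop("duplicate pas_id within gene: ", key[duplicated(key)][1L])
  }
  by_gene <- split(seq_len(nrow(annotations)), annotations$gene_id)
  for (idx in by_gene) {
    if (length(unique(annotations$chrom[idx])) > 1L ||
        length(unique(annotations$strand[idx])) > 1L) {
      stop("all PASs of a gene must share chrom and strand (gene ",
           annotations$gene_id[idx[1L]], ")")
    }
    r <- sort(annotations$utr_rank[idx][annotations$region_class[idx] == "utr3"])
    if (length(r) && !identical(as.integer(r), seq_along(r))) {
      stop("utr_rank must be a contiguous 1..m sequence (gene ",
           annotations$gene_id[idx[1L]], ")")
    }
  }
  invisible(annotations)
}

validate_counts <- function(counts) {
  req <- c("sample", "tissue", "replicate", "gene_id", "pas_id",
           "channel", "count")
  miss <- setdiff(req, names(counts))
  if (length(miss)) {
    stop("counts table is missing columns: ", paste(miss, collapse = ", "))
  }
  if (!all(counts$channel %in% CHANNELS)) {
    stop("channel must be one of: ", paste(CHANNELS, collapse = ", "))
  }
  if (any(counts$count < 0) || any(counts$count != floor(counts$count))) {
    stop("counts must be non-negative integers")
  }
  invisible(counts)
}

# ---- counts cube -----------------------------------------------------------

# Reshape the long counts table into per-gene pas x sample x channel arrays,
# the layout every statistics stage iterates over. Sample order is fixed to
# (tissue, replicate); PAS order follows the annotation's coordinate order
# when given, else lexicographic.
build_cube <- function(counts, annotations = NULL) {
  validate_counts(counts)
  key <- paste(counts$gene_id, counts$pas_id, counts$sample, counts$channel,
               sep = "\r")
  if (anyDuplicated(key)) {
    agg <- rowsum(counts$count, key, reorder = FALSE)
    counts <- counts[!duplicated(key), , drop = FALSE]
    counts$count <- agg[match(unique(key), rownames(agg)), 1L]
  }
  samp <- unique(data.frame(sample = counts$sample, tissue = counts$tissue,
                            replicate = counts$replicate,
                            stringsAsFactors = FALSE))
  samp <- samp[order(samp$tissue, samp$replicate), , drop = FALSE]
  rownames(samp) <- NULL
  s_idx <- match(counts$sample, samp$sample)

  pas_order <- NULL
  if (!is.null(annotations)) {
    ann <- annotations[order(annotations$gene_id, annotations$cleavage_pos), ]
    pas_order <- split(ann$pas_id, ann$gene_id)
  }

  rows_by_gene <- split(seq_len(nrow(counts)), counts$gene_id)
  ch_idx <- match(counts$channel, CHANNELS)
  genes <- names(rows_by_gene)
  arrs <- vector("list", length(genes))
  names(arrs) <- genes
  for (g in genes) {
    idx <- rows_by_gene[[g]]
    pas <- pas_order[[g]] %||% sort(unique(counts$pas_id[idx]))
    a <- array(0L, dim = c(length(pas), nrow(samp), length(CHANNELS)),
               dimnames = list(pas, samp$sample, CHANNELS))
    p <- match(counts$pas_id[idx], pas)
    if (anyNA(p)) stop("counts refer to PAS absent from annotation (gene ", g, ")")
    a[cbind(p, s_idx[idx], ch_idx[idx])] <-
      a[cbind(p, s_idx[idx], ch_idx[idx])] + as.integer(counts$count[idx])
    arrs[[g]] <- a
  }
  list(samples = samp, genes = genes, arrays = arrs)
}

# Total (channel-summed) pas x sample matrix for one gene array.
cube_total <- function(a) {
  m <- a[, , "B6", drop = FALSE] + a[, , "SPR", drop = FALSE] +
    a[, , "common", drop = FALSE]
  dim(m) <- dim(a)[1:2]
  dimnames(m) <- dimnames(a)[1:2]
  m
}

# Column indices of a cube's samples belonging to one tissue.
tissue_cols <- function(cube, tissue) which(cube$samples$tissue == tissue)
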