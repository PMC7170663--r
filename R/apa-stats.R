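# APA diversity and variability statistics: Shannon entropy of PAS usage,
# max-norm replicate variability, mock-replicate (label-shuffling) adjusted
# variability, adjusted between-tissue differences, and switch scores.
#
# Mock replicates are drawn by multivariate-hypergeometric partitioning of
# the pooled PAS-labelled reads, the exact without-replacement equivalent of
# shuffling labelled reads into groups with the original per-replicate gene
# totals.

#' Shannon diversity index of a usage vector
#'
#' `-sum(p_i * ln p_i)` in nats; zero-usage terms contribute 0.
#'
#' @param p numeric usage vector (non-negative, summing to 1).
#' @return Non-negative scalar; 0 iff one PAS carries all usage.
#' @export
shannon_index <- function(p) {
  if (any(p < 0) || abs(sum(p) - 1) > 1e-6) {
    stop("p must be a usage vector summing to 1")
  }
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Replicate variability of PAS usage
#'
#' The maximum over replicate pairs of the Chebyshev (maximum-component)
#' norm of the usage-vector difference; in [0, 1].
#'
#' @param usage matrix of usages, PASs in rows and replicates in columns
#'   (>= 2 columns over an identical PAS set), or a list of equally named
#'   usage vectors.
#' @return Scalar variability in [0, 1].
#' @export
replicate_variability <- function(usage) {
  if (is.list(usage)) {
    nm <- lapply(usage, names)
    if (!all(vapply(nm, identical, TRUE, y = nm[[1L]]))) {
      stop("usage vectors must cover identical PAS sets")
    }
    usage <- do.call(cbind, usage)
  }
  if (ncol(usage) < 2L) stop("need at least two replicates")
  pairs <- utils::combn(ncol(usage), 2L)
  max(vapply(seq_len(ncol(pairs)), function(i) {
    max(abs(usage[, pairs[1L, i]] - usage[, pairs[2L, i]]))
  }, 0))
}

#' Mock replicate count sets
#'
#' Pools one gene's PAS-labelled reads over its replicates and randomly
#' re-partitions them into groups whose per-replicate gene totals equal the
#' originals.
#'
#' @param counts integer matrix, PASs in rows, replicates in columns.
#' @param n_mock number of mock sets (default 100).
#' @param seed integer seed.
#' @return Integer array PAS x replicate x mock; every mock's column sums
#'   equal the original column sums.
#' @export
mock_replicates <- function(counts, n_mock = 100L, seed = 1L) {
  if (ncol(counts) < 2L) stop("need at least two replicates")
  set.seed(fan_seed(seed, "mock_replicates"))
  arr <- partition_counts(rowSums(counts), colSums(counts), n_mock)
  dimnames(arr) <- list(rownames(counts), colnames(counts), NULL)
  arr
}

# usage matrix from a count matrix; columns with zero total dropped
usage_matrix <- function(counts) {
  cs <- colSums(counts)
  counts[, cs > 0, drop = FALSE] %*% diag(1 / cs[cs > 0], nrow = sum(cs > 0))
}

# column maxima of a matrix (fast path via max.col)
col_max <- function(m) {
  m[cbind(max.col(t(m), ties.method = "first"), seq_len(ncol(m)))]
}

# variability of every mock in a pas x rep x mock array, vectorized over
# mocks via pairwise max-abs usage differences
mock_variabilities <- function(arr) {
  k <- dim(arr)[1L]
  R <- dim(arr)[2L]
  n_mock <- dim(arr)[3L]
  totals <- .colSums(arr[, , 1L], k, R)
  u <- arr / rep(rep(totals, each = k), times = n_mock)
  pairs <- utils::combn(R, 2L)
  best <- rep(-Inf, n_mock)
  for (i in seq_len(ncol(pairs))) {
    d <- matrix(u[, pairs[1L, i], ] - u[, pairs[2L, i], ], nrow = k)
    best <- pmax(best, col_max(abs(d)))
  }
  best
}

#' Mock-adjusted replicate variability
#'
#' Observed max-norm variability minus the mean variability of `n_mock` mock
#' replicate sets; near zero for genes whose replicate scatter is pure
#' multinomial sampling noise, positive for genuine replicate
#' heterogeneity. May be negative.
#'
#' @param counts integer matrix, PASs in rows, replicates in columns.
#' @param n_mock mock iterations (default 100).
#' @param seed integer seed.
#' @return List with `var` (raw), `mock_mean`, and `adjusted`.
#' @export
adjusted_variability <- function(counts, n_mock = 100L, seed = 1L) {
  if (any(colSums(counts) == 0)) {
    return(list(var = NA_real_, mock_mean = NA_real_, adjusted = NA_real_))
  }
  v <- replicate_variability(usage_matrix(counts))
  if (nrow(counts) == 1L) {
    return(list(var = 0, mock_mean = 0, adjusted = 0))
  }
  arr <- mock_replicates(counts, n_mock = n_mock, seed = seed)
  mm <- mean(mock_variabilities(arr))
  list(var = v, mock_mean = mm, adjusted = v - mm)
}

#' Mock-adjusted APA difference between two tissues
#'
#' The raw difference is the Chebyshev norm between the two tissue-level
#' usage vectors (replicates pooled). Mocks pool all reads of both tissues
#' and re-partition them preserving the per-tissue gene totals; the adjusted
#' difference subtracts the mock mean.
#'
#' @param counts_a,counts_b integer matrices (PAS x replicates) for the two
#'   tissues, rows covering the same PAS set in the same order.
#' @param n_mock mock iterations (default 100).
#' @param seed integer seed.
#' @return List with `raw`, `mock_mean`, `adjusted`.
#' @export
adjusted_tissue_difference <- function(counts_a, counts_b, n_mock = 100L,
                                       seed = 1L) {
  ta <- rowSums(counts_a)
  tb <- rowSums(counts_b)
  if (length(ta) != length(tb)) stop("PAS sets must match between tissues")
  na <- sum(ta)
  nb <- sum(tb)
  if (na == 0 || nb == 0) stop("gene must have reads in both tissues")
  raw <- max(abs(ta / na - tb / nb))
  if (length(ta) == 1L) return(list(raw = 0, mock_mean = 0, adjusted = 0))
  set.seed(fan_seed(seed, "tissue_diff"))
  arr <- partition_counts(ta + tb, c(na, nb), n_mock)
  d <- matrix(arr[, 1L, ] / na - arr[, 2L, ] / nb, nrow = length(ta))
  mm <- mean(col_max(abs(d)))
  list(raw = raw, mock_mean = mm, adjusted = raw - mm)
}

#' Switch score of a gene
#'
#' The maximum mock-adjusted APA difference over all pairs of expressing
#' tissues; `NA` for genes expressed in fewer than two tissues.
#'
#' @param counts_by_tissue named list of PAS x replicate count matrices, one
#'   per expressing tissue, rows aligned.
#' @param n_mock mock iterations per tissue pair (default 100).
#' @param seed integer seed (fanned out per pair).
#' @return List with `score`, the maximizing `pair`, and the per-pair table
#'   `pairs` (`tissue_a`, `tissue_b`, `raw`, `adjusted`).
#' @export
switch_score <- function(counts_by_tissue, n_mock = 100L, seed = 1L) {
  tt <- names(counts_by_tissue)
  if (length(tt) < 2L) {
    return(list(score = NA_real_, pair = c(NA_character_, NA_character_),
                pairs = data.frame(tissue_a = character(),
                                   tissue_b = character(), raw = numeric(),
                                   adjusted = numeric())))
  }
  pr <- utils::combn(length(tt), 2L)
  raw <- adj <- numeric(ncol(pr))
  for (i in seq_len(ncol(pr))) {
    d <- adjusted_tissue_difference(counts_by_tissue[[pr[1L, i]]],
                                    counts_by_tissue[[pr[2L, i]]],
                                    n_mock = n_mock,
                                    seed = fan_seed(seed, "switch_pair", i))
    raw[i] <- d$raw
    adj[i] <- d$adjusted
  }
  pairs <- data.frame(tissue_a = tt[pr[1L, ]], tissue_b = tt[pr[2L, ]],
                      raw = raw, adjusted = adj, stringsAsFactors = FALSE)
  best <- which.max(pairs$adjusted)
  list(score = pairs$adjusted[best],
       pair = c(pairs$tissue_a[best], pairs$tissue_b[best]), pairs = pairs)
}

#' Per-gene APA diversity statistics across a dataset
#'
#' Engine applying [shannon_index()], [adjusted_variability()] and
#' [switch_score()] to every expressed gene: Shannon index per expressing
#' tissue (tissue-pooled usage), adjusted replicate variability per
#' expressing tissue, and the switch score over expressing tissue pairs.
#' Only used PASs enter any usage vector.
#'
#' @param counts long counts `data.frame`.
#' @param used used-PAS table from [filter_used_pas()].
#' @param expressed per-tissue expressed-gene sets from
#'   [filter_expressed_genes()].
#' @param annotations annotation `data.frame` (fixes PAS order).
#' @param n_mock mock iterations (default 100).
#' @param seed integer seed.
#' @return List of data frames: `diversity` (gene x tissue: `shannon`,
#'   `var`, `mock_mean`, `adjusted_var`), `switch` (per gene: `switch_score`,
#'   maximizing pair), `pairs` (per gene x tissue pair: raw and adjusted
#'   difference).
#' @export
diversity_stats <- function(counts, used, expressed, annotations,
                            n_mock = 100L, seed = 1L) {
  cc <- restrict_to_used(counts, used)
  cube <- build_cube(cc, annotations)
  tcols <- lapply(stats::setNames(nm = names(expressed)),
                  function(t) tissue_cols(cube, t))
  d_gene <- d_tissue <- character()
  d_sh <- d_var <- d_mm <- d_adj <- numeric()
  s_gene <- s_ta <- s_tb <- character()
  s_score <- numeric()
  pair_rows <- list()
  for (gi in seq_along(cube$genes)) {
    g <- cube$genes[gi]
    a <- cube_total(cube$arrays[[g]])
    exp_t <- names(expressed)[vapply(expressed, function(x) g %in% x, TRUE)]
    if (!length(exp_t)) next
    per_t <- list()
    for (ti in seq_along(exp_t)) {
      t <- exp_t[ti]
      m <- a[, tcols[[t]], drop = FALSE]
      per_t[[t]] <- m
      pooled <- rowSums(m)
      av <- adjusted_variability(m, n_mock = n_mock,
                                 seed = fan_seed(seed, "adjvar", gi * 1000L + ti))
      d_gene <- c(d_gene, g)
      d_tissue <- c(d_tissue, t)
      d_sh <- c(d_sh, shannon_index(pooled / sum(pooled)))
      d_var <- c(d_var, av$var)
      d_mm <- c(d_mm, av$mock_mean)
      d_adj <- c(d_adj, av$adjusted)
    }
    sw <- switch_score(per_t, n_mock = n_mock, seed = fan_seed(seed, "switch", gi))
    s_gene <- c(s_gene, g)
    s_score <- c(s_score, sw$score)
    s_ta <- c(s_ta, sw$pair[1L])
    s_tb <- c(s_tb, sw$pair[2L])
    if (nrow(sw$pairs)) {
      pair_rows[[g]] <- cbind(gene_id = g, sw$pairs, stringsAsFactors = FALSE)
    }
  }
  pairs <- if (length(pair_rows)) {
    r <- do.call(rbind, pair_rows)
    rownames(r) <- NULL
    r
  } else {
    data.frame(gene_id = character(), tissue_a = character(),
               tissue_b = character(), raw = numeric(), adjusted = numeric())
  }
  list(
    diversity = data.frame(gene_id = d_gene, tissue = d_tissue, shannon = d_sh,
                           var = d_var, mock_mean = d_mm, adjusted_var = d_adj,
                           stringsAsFactors = FALSE),
    switch = data.frame(gene_id = s_gene, switch_score = s_score,
                        tissue_a = s_ta, tissue_b = s_tb,
                        stringsAsFactors = FALSE),
    pairs = pairs)
}
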