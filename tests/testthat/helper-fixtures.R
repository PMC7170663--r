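# Shared fixture builders and independent brute-force oracles.

# one long-format counts row
cnt_row <- function(sample, tissue, replicate, gene, pas, channel, count) {
  data.frame(sample = sample, tissue = tissue, replicate = replicate,
             gene_id = gene, pas_id = pas, channel = channel, count = count,
             stringsAsFactors = FALSE)
}

# counts for one gene: `mat` is PAS x replicate (single tissue), channel fixed
gene_counts <- function(gene, tissue, mat, channel = "common",
                        pas = paste0("p", seq_len(nrow(mat)))) {
  rows <- list()
  for (r in seq_len(ncol(mat))) {
    for (i in seq_len(nrow(mat))) {
      rows[[length(rows) + 1L]] <- cnt_row(
        paste0(tissue, "_r", r), tissue, r, gene, pas[i], channel, mat[i, r])
    }
  }
  do.call(rbind, rows)
}

# minimal annotation table: one gene, PASs at the given coords
ann_gene <- function(gene, coords, chrom = "chr1", strand = "+",
                     region = rep("utr3", length(coords)),
                     pas = paste0("p", seq_along(coords))) {
  ann <- data.frame(gene_id = gene, pas_id = pas, chrom = chrom,
                    strand = strand, cleavage_pos = as.integer(coords),
                    region_class = region, utr_rank = NA_integer_,
                    stringsAsFactors = FALSE)
  allelicAPA:::derive_utr_rank(ann)
}

# brute-force max-norm over replicate pairs (independent of the package path)
brute_variability <- function(usage) {
  best <- 0
  for (i in seq_len(ncol(usage))) {
    for (j in seq_len(ncol(usage))) {
      if (i < j) {
        for (k in seq_len(nrow(usage))) {
          best <- max(best, abs(usage[k, i] - usage[k, j]))
        }
      }
    }
  }
  best
}

# brute-force Benjamini-Hochberg step-up
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  prev <- 1
  for (i in n:1) {
    val <- min(prev, n * p[o[i]] / i)
    adj[o[i]] <- val
    prev <- val
  }
  adj
}

# exhaustive affine-gap global alignment score by recursive enumeration of
# move sequences (match / gap-in-b / gap-in-a with gap-run state)
enum_align_score <- function(a, b, S, gap_open, gap_extend) {
  av <- strsplit(a, "")[[1L]]
  bv <- strsplit(b, "")[[1L]]
  rec <- function(i, j, last) {
    if (i > length(av) && j > length(bv)) return(0)
    best <- -Inf
    if (i <= length(av) && j <= length(bv)) {
      best <- max(best, S[av[i], bv[j]] + rec(i + 1L, j + 1L, "M"))
    }
    if (i <= length(av)) {
      best <- max(best, (if (last == "X") gap_extend else gap_open) +
                    rec(i + 1L, j, "X"))
    }
    if (j <= length(bv)) {
      best <- max(best, (if (last == "Y") gap_extend else gap_open) +
                    rec(i, j + 1L, "Y"))
    }
    best
  }
  rec(1L, 1L, "start")
}

blosum62 <- function() allelicAPA:::the_blosum62()

# allelic-usage structure for clustering tests: one feature PAS per gene,
# usage value per tissue x allele from `value_fun(gene, tissue, allele)`
cluster_fixture <- function(n_genes, tissues, value_fun) {
  rows <- list()
  for (g in paste0("g", seq_len(n_genes))) {
    for (t in tissues) {
      for (al in c("B6", "SPR")) {
        v <- value_fun(g, t, al)
        rows[[paste(g, t, al)]] <- data.frame(
          gene_id = g, tissue = t, allele = al,
          pas_id = c(paste0(g, "_p1"), paste0(g, "_p2")),
          usage = c(v, 1 - v), total_reads = 1000, stringsAsFactors = FALSE)
      }
    }
  }
  testable <- expand.grid(gene_id = paste0("g", seq_len(n_genes)),
                          tissue = tissues, stringsAsFactors = FALSE)
  list(usage = do.call(rbind, rows), testable = testable)
}

# all permutations of 1..n (small n), for exact permutation-test oracles
combinat_perms <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- combinat_perms(n - 1)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  r <- 1L
  for (i in seq_len(n)) {
    for (j in seq_len(nrow(sub))) {
      out[r, ] <- append(sub[j, ], n, after = i - 1L)
      r <- r + 1L
    }
  }
  out
}

# allele-channel counts for one gene x tissue: per-allele usage vectors and
# per-replicate per-allele read depth (exact, deterministic rounding)
allelic_gene_counts <- function(gene, tissue, p_b6, p_spr, depth,
                                n_rep = 3L,
                                pas = paste0("p", seq_along(p_b6))) {
  rows <- list()
  for (r in seq_len(n_rep)) {
    nb <- round(p_b6 * depth)
    ns <- round(p_spr * depth)
    for (i in seq_along(pas)) {
      rows[[length(rows) + 1L]] <- cnt_row(paste0(tissue, "_r", r), tissue, r,
                                           gene, pas[i], "B6", nb[i])
      rows[[length(rows) + 1L]] <- cnt_row(paste0(tissue, "_r", r), tissue, r,
                                           gene, pas[i], "SPR", ns[i])
    }
  }
  do.call(rbind, rows)
}
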