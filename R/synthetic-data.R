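# Synthetic allele-labelled 3'-end count data with known ground truth.
#
# The generator emulates the statistical structure the downstream analysis
# assumes: multinomial PAS sampling per replicate, tissue-dependent usage
# vectors built from truth archetypes (single / F1-like / F2-like /
# switch-like), a cis-divergence usage shift between the two parental alleles,
# a configurable allelic-assignability rate, and an inverse coupling between
# expression level and minor-PAS "error" usage.

#' Simulation configuration
#'
#' Defaults describe a nine-tissue F1-hybrid 3' mRNA-seq study with three
#' biological replicates per tissue. `pas_per_gene_dist` carries 20% mass at
#' one PAS (realized single-PAS genes); `class_fractions` renormalizes the
#' observed composition of expressed genes over the four representable truth
#' archetypes.
#'
#' @param n_genes number of simulated genes (> 0).
#' @param tissues character vector of tissue labels.
#' @param n_replicates biological replicates per tissue (>= 2).
#' @param pas_per_gene_dist named probability vector over PAS counts 1..8.
#' @param class_fractions named fractions over truth classes
#'   `single`, `f1`, `f2`, `switch`; must sum to 1. `single` is realized via
#'   the mass of `pas_per_gene_dist` at one PAS; multi-PAS genes draw their
#'   class from the remaining fractions, renormalized.
#' @param divergent_fraction fraction of multi-PAS genes given an allelic
#'   usage shift.
#' @param divergence_effect usage shift magnitude on the dominant PAS, in
#'   [0, 1].
#' @param allelic_rate probability that a read is allele-assignable (split
#'   equally between B6 and SPR origin); the remainder lands in the common
#'   channel.
#' @param libsize_mean expected gene-level reads per replicate; expected
#'   expression is log-normal across genes around this mean.
#' @param libsize_sigma sdlog of the across-gene expression distribution.
#' @param error_slope strength of the inverse expression/minor-usage
#'   coupling (0 disables it).
#' @param seed master integer seed for all generator stages.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_genes = 500L,
                       tissues = c("ESC", "CER", "COR", "HEA", "KID",
                                   "LIV", "LUN", "MUS", "SPL"),
                       n_replicates = 3L,
                       pas_per_gene_dist = c(`1` = 0.20, `2` = 0.30,
                                             `3` = 0.22, `4` = 0.13,
                                             `5` = 0.07, `6` = 0.04,
                                             `7` = 0.025, `8` = 0.015),
                       class_fractions = c(single = 0.20, f1 = 0.31,
                                           f2 = 0.41, switch = 0.08),
                       divergent_fraction = 0.20,
                       divergence_effect = 0.30,
                       allelic_rate = 0.30,
                       libsize_mean = 2000,
                       libsize_sigma = 1,
                       error_slope = 1,
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), tissues = as.character(tissues),
              n_replicates = as.integer(n_replicates),
              pas_per_gene_dist = pas_per_gene_dist,
              class_fractions = class_fractions,
              divergent_fraction = divergent_fraction,
              divergence_effect = divergence_effect,
              allelic_rate = allelic_rate, libsize_mean = libsize_mean,
              libsize_sigma = libsize_sigma, error_slope = error_slope,
              seed = as.integer(seed))
  if (cfg$n_genes < 1L) stop("n_genes must be positive")
  if (length(cfg$tissues) < 1L) stop("at least one tissue is required")
  if (cfg$n_replicates < 2L) stop("n_replicates must be >= 2")
  d <- cfg$pas_per_gene_dist
  if (is.null(names(d)) || any(d < 0) || abs(sum(d) - 1) > 1e-6) {
    stop("pas_per_gene_dist must be a named non-negative vector summing to 1")
  }
  f <- cfg$class_fractions
  if (!all(c("single", "f1", "f2", "switch") %in% names(f)) ||
      any(f < 0) || any(f > 1) || abs(sum(f) - 1) > 1e-6) {
    stop("class_fractions must cover single/f1/f2/switch, lie in [0,1] and sum to 1")
  }
  for (nm in c("divergent_fraction", "divergence_effect", "allelic_rate")) {
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1) stop(nm, " must be in [0, 1]")
  }
  if (cfg$libsize_mean <= 0) stop("libsize_mean must be positive")
  structure(cfg, class = "sim_config")
}

#' Simulate PAS gene models
#'
#' Draws each gene's PAS count from `pas_per_gene_dist` and lays the PASs out
#' on one strand with strictly ordered coordinates at least 50 nt apart, so
#' the 24-nt read-assignment windows of one gene never overlap. With two or
#' more PASs, the transcriptionally first site is labelled `upstream` (of the
#' last stop codon) with probability 0.2; all other sites are 3'UTR PASs with
#' contiguous `utr_rank` in 5'->3' transcriptional order.
#'
#' @param config a [sim_config()].
#' @return A PAS annotation `data.frame` (columns `gene_id`, `pas_id`,
#'   `chrom`, `strand`, `cleavage_pos`, `region_class`, `utr_rank`).
#' @export
simulate_gene_models <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_genes < 1L) stop("n_genes must be positive")
  set.seed(fan_seed(config$seed, "models"))
  n <- config$n_genes
  wid <- max(4L, nchar(as.character(n)))
  gene_ids <- sprintf(paste0("gene%0", wid, "d"), seq_len(n))
  ks <- sample(as.integer(names(config$pas_per_gene_dist)), n, replace = TRUE,
               prob = config$pas_per_gene_dist)
  chroms <- paste0("chr", 1L + (seq_len(n) - 1L) %% 19L)
  base <- 1e6 * (1L + (seq_len(n) - 1L) %/% 19L)
  strands <- sample(c("+", "-"), n, replace = TRUE)

  out <- vector("list", n)
  for (i in seq_len(n)) {
    k <- ks[i]
    gaps <- if (k > 1L) sample(50:500, k - 1L, replace = TRUE) else integer()
    pos <- as.integer(base[i] + cumsum(c(0L, gaps)))
    # transcriptional 5'->3' order: ascending coords on +, descending on -
    tx_order <- if (strands[i] == "+") seq_len(k) else rev(seq_len(k))
    region <- rep("utr3", k)
    if (k >= 2L && stats::runif(1) < 0.2) region[tx_order[1L]] <- "upstream"
    utr_rank <- rep(NA_integer_, k)
    utr_tx <- tx_order[region[tx_order] == "utr3"]
    utr_rank[utr_tx] <- seq_along(utr_tx)
    pas_id <- character(k)
    pas_id[tx_order] <- sprintf("%s:PAS%d", gene_ids[i], seq_len(k))
    out[[i]] <- data.frame(gene_id = gene_ids[i], pas_id = pas_id,
                           chrom = chroms[i], strand = strands[i],
                           cleavage_pos = pos, region_class = region,
                           utr_rank = utr_rank, stringsAsFactors = FALSE)
  }
  ann <- do.call(rbind, out)
  rownames(ann) <- NULL
  validate_annotations(ann)
  ann
}

# Distribute `mass` over `k` slots with mild random unevenness.
rand_split <- function(mass, k) {
  if (k == 0L) return(numeric())
  w <- stats::runif(k, 0.5, 1.5)
  mass * w / sum(w)
}

# Usage vector for one tissue given the gene's archetype. `slots` indexes PASs
# in transcriptional order; returns usages aligned to that order.
archetype_usage <- function(class, k, g_err, designated, tissue_in_a = TRUE) {
  if (k == 1L) return(1)
  p <- numeric(k)
  if (class == "f1") {
    p_dom <- 0.93 + (1 - g_err) * stats::runif(1, 0.04, 0.065)
    p[designated$dom] <- p_dom
    # residual usage is rank-skewed: a rank-2 minor carries most of it
    rest <- 1 - p_dom
    minors <- if (k == 2L) rest else c(0.7 * rest, rand_split(0.3 * rest, k - 2L))
    p[-designated$dom] <- minors
  } else if (class == "f2") {
    gap <- if (designated$hit) stats::runif(1, 0, 0.12) else stats::runif(1, 0.05, 0.35)
    M <- if (k == 2L) 1 else 0.97 - 0.22 * g_err
    u1 <- (M + gap) / 2
    u2 <- (M - gap) / 2
    rest <- 1 - M
    minors <- rand_split(rest, k - 2L)
    # keep the designated pair as ranks 1 and 2
    if (length(minors) && max(minors) >= u2) {
      surplus <- sum(minors) - 0.8 * u2 * sum(minors) / max(minors)
      minors <- minors * 0.8 * u2 / max(minors)
      u1 <- u1 + surplus / 2
      u2 <- u2 + surplus / 2
    }
    p[designated$dom] <- u1
    p[designated$sec] <- u2
    p[-c(designated$dom, designated$sec)] <- minors
  } else if (class == "switch") {
    h <- 0.75 + 0.15 * (1 - g_err)
    delta <- designated$delta
    mm <- if (k > 2L) 0.05 else 0
    if (tissue_in_a) {
      a <- h
      b <- (1 - h - mm)
    } else {
      a <- h - delta
      b <- 1 - a - mm
    }
    p[designated$dom] <- a
    p[designated$sec] <- b
    if (k > 2L) p[-c(designated$dom, designated$sec)] <- rand_split(mm, k - 2L)
  } else {
    stop("unknown archetype: ", class)
  }
  p / sum(p)
}

#' Simulate ground-truth usage profiles
#'
#' Assigns each gene a truth class (single-PAS genes are `single`; multi-PAS
#' genes draw from the `f1`/`f2`/`switch` fractions), an expected expression
#' level, and per tissue x allele true usage vectors honouring the class
#' guarantees: F1-like genes keep dominant usage >= 0.93 in every tissue,
#' F2-like genes have a rank-1/rank-2 usage gap <= 0.12 in at least one
#' tissue, switch-like genes move one PAS by >= 0.6 between a designated
#' tissue pair. Minor-PAS "error" usage grows as expected expression falls,
#' at a rate set by `error_slope`. A `divergent_fraction` of multi-PAS genes
#' receives a between-allele shift of `divergence_effect` on the dominant PAS
#' (B6 is the reference allele; shift direction is randomized).
#'
#' @param config a [sim_config()].
#' @param models annotation table from [simulate_gene_models()].
#' @return An object of class `sim_truth`: list with `genes` (per-gene truth
#'   labels), `usage` (gene x tissue x allele x PAS true usages), `tissues`,
#'   and the generating `config`.
#' @export
simulate_usage_profiles <- function(config, models) {
  stopifnot(inherits(config, "sim_config"))
  validate_annotations(models)
  set.seed(fan_seed(config$seed, "profiles"))
  tissues <- config$tissues
  ann <- models[order(models$gene_id, models$cleavage_pos), ]
  by_gene <- split(ann, ann$gene_id)
  gene_ids <- names(by_gene)
  n <- length(gene_ids)
  ks <- vapply(by_gene, nrow, 0L)

  cf <- config$class_fractions[c("f1", "f2", "switch")]
  classes <- ifelse(ks == 1L, "single", NA)
  multi <- which(ks > 1L)
  if (length(multi)) {
    classes[multi] <- sample(names(cf), length(multi), replace = TRUE,
                             prob = cf / sum(cf))
  }

  expr <- stats::rlnorm(n, meanlog = log(config$libsize_mean) -
                          config$libsize_sigma^2 / 2,
                        sdlog = config$libsize_sigma)
  g_err <- 1 / (1 + (expr / config$libsize_mean)^config$error_slope)

  usage <- vector("list", n)
  gene_rows <- vector("list", n)
  for (i in seq_len(n)) {
    g <- gene_ids[i]
    k <- ks[i]
    a <- by_gene[[g]]
    # PAS ids in transcriptional order
    tx <- if (a$strand[1L] == "+") order(a$cleavage_pos) else order(-a$cleavage_pos)
    pas <- a$pas_id[tx]
    cls <- classes[i]
    des <- list(dom = 1L, sec = if (k > 1L) 2L else NA_integer_, hit = FALSE,
                delta = NA_real_)
    f2_tissue <- switch_a <- switch_b <- NA_character_
    if (cls == "f1" && k > 1L) des$dom <- sample.int(k, 1L)
    if (cls == "f2") {
      pair <- sample.int(k, 2L)
      des$dom <- pair[1L]; des$sec <- pair[2L]
      f2_tissue <- sample(tissues, 1L)
    }
    if (cls == "switch") {
      h_max <- 0.75 + 0.15 * (1 - g_err[i])
      des$delta <- stats::runif(1, 0.6, min(0.73, h_max - 0.02))
      n_a <- sample.int(max(1L, length(tissues) - 1L), 1L)
      in_a <- seq_along(tissues) %in% sample(seq_along(tissues), n_a)
      switch_a <- tissues[which(in_a)[1L]]
      switch_b <- tissues[which(!in_a)[1L]]
    }
    pmat <- matrix(0, nrow = k, ncol = length(tissues),
                   dimnames = list(pas, tissues))
    for (t in seq_along(tissues)) {
      if (cls == "single") {
        pmat[, t] <- 1
      } else if (cls == "switch") {
        pmat[, t] <- archetype_usage(cls, k, g_err[i], des, tissue_in_a = in_a[t])
      } else {
        des$hit <- (cls == "f2") && identical(tissues[t], f2_tissue)
        pmat[, t] <- archetype_usage(cls, k, g_err[i], des)
      }
    }
    usage[[i]] <- pmat
    gene_rows[[i]] <- data.frame(
      gene_id = g, k = k, class = cls, divergent = FALSE,
      expected_expression = expr[i], error_intensity = g_err[i],
      dom_pas = pas[des$dom],
      f2_tissue = if (cls == "f2") f2_tissue else NA_character_,
      switch_tissue_a = switch_a, switch_tissue_b = switch_b,
      switch_pas = if (cls == "switch") pas[des$dom] else NA_character_,
      switch_delta = if (cls == "switch") des$delta else NA_real_,
      stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, gene_rows)
  rownames(genes) <- NULL

  # allelic divergence: shift the per-tissue dominant PAS of the SPR allele.
  # An additive usage shift is only realizable on genes with moderate
  # dominant usage (a 0.95-usage PAS cannot gain 0.3, and losing 0.3 would
  # break the F1/switch class guarantees in the allele mixture), so
  # divergence is assigned among the f2-like genes -- matching the
  # observation that allelic usage differences concentrate at moderate
  # major-PAS usage.
  eff <- config$divergence_effect
  eligible <- which(classes == "f2" &
                      vapply(usage, function(m) max(m) >= eff / 2 + 0.02, TRUE))
  n_div <- round(config$divergent_fraction * sum(ks > 1L))
  div_idx <- if (n_div > 0L && length(eligible)) {
    sample(eligible, min(n_div, length(eligible)))
  } else integer()
  genes$divergent[div_idx] <- TRUE

  rows <- vector("list", 2L * n)
  for (i in seq_len(n)) {
    m_b6 <- usage[[i]]
    m_spr <- m_b6
    if (genes$divergent[i]) {
      # SPR loses `eff` usage on the per-tissue dominant PAS (clamped away
      # from 0); the freed mass goes to the other PASs proportionally.
      for (t in seq_len(ncol(m_b6))) {
        p <- m_b6[, t]
        dom <- which.max(p)
        target <- max(p[dom] - eff, 0.01)
        q <- p
        q[dom] <- target
        if (length(p) > 1L) {
          q[-dom] <- p[-dom] * (1 - target) / (1 - p[dom])
        }
        m_spr[, t] <- q / sum(q)
      }
    }
    g <- genes$gene_id[i]
    pas <- rownames(m_b6)
    tt <- colnames(m_b6)
    rows[[2L * i - 1L]] <- data.frame(
      gene_id = g, tissue = rep(tt, each = length(pas)), allele = "B6",
      pas_id = rep(pas, times = length(tt)), usage = as.vector(m_b6),
      stringsAsFactors = FALSE)
    rows[[2L * i]] <- data.frame(
      gene_id = g, tissue = rep(tt, each = length(pas)), allele = "SPR",
      pas_id = rep(pas, times = length(tt)), usage = as.vector(m_spr),
      stringsAsFactors = FALSE)
  }
  usage_df <- do.call(rbind, rows)
  rownames(usage_df) <- NULL
  structure(list(genes = genes, usage = usage_df, tissues = tissues,
                 config = config),
            class = "sim_truth")
}

#' Simulate allele-channel PAS read counts
#'
#' Per gene and replicate the gene total is log-normal around the gene's
#' expected expression (sdlog 0.25 replicate noise); reads split to parental
#' alleles as Binomial(n, 1/2); each allelic read is observed in its allele
#' channel with probability `allelic_rate`, otherwise in the common channel;
#' PAS identity is multinomial in the originating allele's true usage vector.
#' Channel totals per gene and replicate conserve the drawn gene total.
#'
#' @param truth a `sim_truth` from [simulate_usage_profiles()].
#' @param config the generating [sim_config()].
#' @return A long counts `data.frame` (columns `sample`, `tissue`,
#'   `replicate`, `gene_id`, `pas_id`, `channel`, `count`); zero cells are
#'   omitted.
#' @export
simulate_counts <- function(truth, config) {
  stopifnot(inherits(truth, "sim_truth"), inherits(config, "sim_config"))
  set.seed(fan_seed(config$seed, "counts"))
  tissues <- config$tissues
  reps <- seq_len(config$n_replicates)
  samples <- data.frame(
    sample = as.vector(t(outer(tissues, reps, function(t, r) paste0(t, "_r", r)))),
    tissue = rep(tissues, each = length(reps)),
    replicate = rep(reps, times = length(tissues)),
    stringsAsFactors = FALSE)

  u_by_gene <- split(truth$usage, truth$usage$gene_id)
  genes <- truth$genes
  acc <- vector("list", nrow(genes) * nrow(samples))
  j <- 0L
  for (i in seq_len(nrow(genes))) {
    g <- genes$gene_id[i]
    u <- u_by_gene[[g]]
    pas <- unique(u$pas_id)
    k <- length(pas)
    # usage matrices pas x tissue per allele
    pm <- list(
      B6 = matrix(u$usage[u$allele == "B6"][
        order(match(u$tissue[u$allele == "B6"], tissues),
              match(u$pas_id[u$allele == "B6"], pas))],
        nrow = k, dimnames = list(pas, tissues)),
      SPR = matrix(u$usage[u$allele == "SPR"][
        order(match(u$tissue[u$allele == "SPR"], tissues),
              match(u$pas_id[u$allele == "SPR"], pas))],
        nrow = k, dimnames = list(pas, tissues)))
    e <- genes$expected_expression[i]
    totals <- pmax(0L, as.integer(round(stats::rlnorm(
      nrow(samples), meanlog = log(e) - 0.25^2 / 2, sdlog = 0.25))))
    for (s in seq_len(nrow(samples))) {
      n_tot <- totals[s]
      if (n_tot == 0L) next
      tis <- samples$tissue[s]
      n_b6 <- stats::rbinom(1L, n_tot, 0.5)
      cnt <- matrix(0L, nrow = k, ncol = 3L,
                    dimnames = list(pas, CHANNELS))
      for (al in c("B6", "SPR")) {
        n_al <- if (al == "B6") n_b6 else n_tot - n_b6
        if (n_al == 0L) next
        by_pas <- as.integer(stats::rmultinom(1L, n_al, pm[[al]][, tis]))
        obs <- stats::rbinom(k, by_pas, config$allelic_rate)
        cnt[, al] <- cnt[, al] + obs
        cnt[, "common"] <- cnt[, "common"] + (by_pas - obs)
      }
      nz <- which(cnt > 0L, arr.ind = TRUE)
      if (nrow(nz) == 0L) next
      j <- j + 1L
      acc[[j]] <- list(s = s, g = g, pas = pas[nz[, 1L]],
                       channel = CHANNELS[nz[, 2L]], count = cnt[nz])
    }
  }
  acc <- acc[seq_len(j)]
  len <- vapply(acc, function(x) length(x$count), 0L)
  s_of <- rep.int(vapply(acc, function(x) x$s, 0L), len)
  counts <- data.frame(
    sample = samples$sample[s_of], tissue = samples$tissue[s_of],
    replicate = samples$replicate[s_of],
    gene_id = rep.int(vapply(acc, function(x) x$g, ""), len),
    pas_id = unlist(lapply(acc, function(x) x$pas), use.names = FALSE),
    channel = unlist(lapply(acc, function(x) x$channel), use.names = FALSE),
    count = unlist(lapply(acc, function(x) x$count), use.names = FALSE),
    stringsAsFactors = FALSE)
  validate_counts(counts)
}

#' Emit per-read 3'-end records for simulated counts
#'
#' Thin emitter for testing read-to-PAS assignment: every counted read becomes
#' one record whose end position is the annotated cleavage position plus a
#' uniform integer offset in [-max_offset, max_offset]. Because simulated PASs
#' are >= 50 nt apart, every emitted read is uniquely assignable.
#'
#' @param counts long counts table from [simulate_counts()].
#' @param annotations matching PAS annotation table.
#' @param max_offset largest absolute end-position offset (default 24).
#' @param seed integer seed.
#' @return A read-end `data.frame` (columns `chrom`, `strand`, `end_pos`,
#'   `sample_id`, `tissue`, `replicate`, `allele_channel`).
#' @export
simulate_read_ends <- function(counts, annotations, max_offset = 24L,
                               seed = 1L) {
  validate_counts(counts)
  validate_annotations(annotations)
  set.seed(fan_seed(seed, "read_ends"))
  key <- paste(annotations$gene_id, annotations$pas_id)
  idx <- match(paste(counts$gene_id, counts$pas_id), key)
  if (anyNA(idx)) stop("counts refer to PAS absent from annotation")
  n <- sum(counts$count)
  row_of <- rep.int(seq_len(nrow(counts)), counts$count)
  offs <- sample.int(2L * max_offset + 1L, n, replace = TRUE) - max_offset - 1L
  data.frame(
    chrom = annotations$chrom[idx][row_of],
    strand = annotations$strand[idx][row_of],
    end_pos = annotations$cleavage_pos[idx][row_of] + offs,
    sample_id = counts$sample[row_of],
    tissue = counts$tissue[row_of],
    replicate = counts$replicate[row_of],
    allele_channel = counts$channel[row_of],
    stringsAsFactors = FALSE)
}

#' Write / read ground-truth tables
#'
#' Serializes a `sim_truth` to TSV (gene table + usage table) plus the
#' generating configuration as YAML, and reads it back losslessly (numeric
#' columns are written with 17 significant digits).
#'
#' @param truth a `sim_truth`.
#' @param path directory to write into (created if absent).
#' @return `write_truth_tables` returns `path` invisibly;
#'   `read_truth_tables` returns a `sim_truth`.
#' @export
write_truth_tables <- function(truth, path) {
  stopifnot(inherits(truth, "sim_truth"))
  if (!dir.exists(path)) {
    ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create directory: ", path)
  }
  fmt <- function(df, cols) {
    for (cc in intersect(cols, names(df))) df[[cc]] <- sprintf("%.17g", df[[cc]])
    df
  }
  utils::write.table(
    fmt(truth$genes, c("expected_expression", "error_intensity", "switch_delta")),
    file.path(path, "truth_genes.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(fmt(truth$usage, "usage"),
                     file.path(path, "truth_usage.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- unclass(truth$config)
  cfg$pas_per_gene_dist <- as.list(cfg$pas_per_gene_dist)
  cfg$class_fractions <- as.list(cfg$class_fractions)
  yaml::write_yaml(cfg, file.path(path, "sim_config.yaml"))
  invisible(path)
}

#' @rdname write_truth_tables
#' @export
read_truth_tables <- function(path) {
  genes <- utils::read.delim(file.path(path, "truth_genes.tsv"),
                             stringsAsFactors = FALSE)
  usage <- utils::read.delim(file.path(path, "truth_usage.tsv"),
                             stringsAsFactors = FALSE)
  cfg <- yaml::read_yaml(file.path(path, "sim_config.yaml"))
  cfg$pas_per_gene_dist <- unlist(cfg$pas_per_gene_dist)
  cfg$class_fractions <- unlist(cfg$class_fractions)
  config <- do.call(sim_config, cfg)
  structure(list(genes = genes, usage = usage,
                 tissues = config$tissues, config = config),
            class = "sim_truth")
}

#' Simulate a complete synthetic dataset
#'
#' Convenience wrapper chaining [simulate_gene_models()],
#' [simulate_usage_profiles()] and [simulate_counts()].
#'
#' @param config a [sim_config()].
#' @return List with `annotations`, `truth`, and `counts`.
#' @export
simulate_apa_dataset <- function(config = sim_config()) {
  models <- simulate_gene_models(config)
  truth <- simulate_usage_profiles(config, models)
  counts <- simulate_counts(truth, config)
  list(annotations = models, truth = truth, counts = counts)
}
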