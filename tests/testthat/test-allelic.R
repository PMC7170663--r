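# Allelic filters, the CMH divergence test, divergence classes,
# scaling-law binning, variant density and allelic clustering.

test_that("coverage filter drops gene-tissues under 10 allelic reads", {
  ok <- allelic_gene_counts("gA", "T1", c(0.6, 0.4), c(0.6, 0.4), depth = 50)
  # gB: one sample has only 9 SPR reads
  low <- rbind(
    allelic_gene_counts("gB", "T1", c(0.6, 0.4), c(0.6, 0.4), depth = 50,
                        n_rep = 2),
    cnt_row("T1_r3", "T1", 3, "gB", c("p1", "p2"), "B6", c(30, 20)),
    cnt_row("T1_r3", "T1", 3, "gB", c("p1", "p2"), "SPR", c(5, 4)))
  af <- allelic_usage_with_filters(rbind(ok, low))
  expect_true(any(af$testable$gene_id == "gA"))
  expect_false(any(af$testable$gene_id == "gB"))
  expect_equal(af$dropped$reason[af$dropped$gene_id == "gB"],
               "low_allelic_coverage")
})

test_that("exclusion list removes genes from allelic analyses", {
  counts <- allelic_gene_counts("gA", "T1", c(0.6, 0.4), c(0.6, 0.4), 50)
  af <- allelic_usage_with_filters(counts, exclusion_list = "gA")
  expect_equal(nrow(af$testable), 0L)
  expect_true("exclusion_list" %in% af$dropped$reason)
})

test_that("consistency filter removes PASs with divergent estimates", {
  # allelic-only usage 0.50; common reads concentrated on p1 push the
  # combined estimate to ~0.65: the gap > 0.10 removes both PASs of k = 2
  counts <- rbind(
    allelic_gene_counts("gA", "T1", c(0.5, 0.5), c(0.5, 0.5), depth = 100),
    gene_counts("gA", "T1", matrix(rep(c(520, 80), 3), nrow = 2),
                channel = "common"))
  af <- allelic_usage_with_filters(counts)
  expect_true(all(c("p1", "p2") %in% af$removed_pas$pas_id))
  expect_gt(af$removed_pas$usage_gap[af$removed_pas$pas_id == "p1"], 0.10)

  # fully assignable reads: the two estimators coincide, nothing is removed
  d <- simulate_apa_dataset(sim_config(n_genes = 40, tissues = c("A", "B"),
                                       allelic_rate = 1, seed = 3))
  af2 <- allelic_usage_with_filters(d$counts)
  expect_equal(nrow(af2$removed_pas), 0L)
})

test_that("CMH reduces to the chi-square closed form on a single stratum", {
  # exact identity: uncorrected CMH = (n-1)/n x Pearson chi-square;
  # the continuity-corrected form matches mantelhaen.test exactly
  set.seed(17)
  n_checked <- 0
  while (n_checked < 25) {
    tab <- matrix(sample(0:30, 4, replace = TRUE), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    n <- sum(tab)
    if (n <= 1) next
    ours <- cmh_test(tab, correct = FALSE)
    pearson <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    expect_equal(ours$statistic, (n - 1) / n * unname(pearson$statistic),
                 tolerance = 1e-12)
    # closed form evaluated directly from the margins
    r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
    c1 <- sum(tab[, 1]); c2 <- sum(tab[, 2])
    num <- tab[1, 1] - r1 * c1 / n
    den <- r1 * r2 * c1 * c2 / (n^2 * (n - 1))
    yates <- if (abs(num) >= 0.5) 0.5 else 0
    cc <- cmh_test(tab, correct = TRUE)
    expect_equal(cc$statistic, (abs(num) - yates)^2 / den, tolerance = 1e-12)
    n_checked <- n_checked + 1
  }
})

test_that("CMH agrees with mantelhaen.test across strata", {
  set.seed(19)
  for (i in 1:10) {
    K <- sample(2:4, 1)
    tab <- array(sample(1:40, 4 * K, replace = TRUE), dim = c(2, 2, K))
    ours <- cmh_test(tab)
    ref <- stats::mantelhaen.test(tab, correct = TRUE)
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$p.value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("degenerate tables give p = 1 with a flag", {
  tab <- array(c(0, 0, 5, 7), dim = c(2, 2, 1)) # zero column margin
  res <- cmh_test(tab)
  expect_true(res$degenerate)
  expect_equal(res$p.value, 1)
})

test_that("BH adjustment matches the brute-force step-up oracle", {
  set.seed(23)
  for (i in 1:20) {
    n <- sample(1:50, 1)
    p <- stats::runif(n)
    expect_equal(stats::p.adjust(p, method = "BH"), bh_oracle(p),
                 tolerance = 1e-12)
  }
})

test_that("divergence calls recover a constructed allelic shift", {
  null_g <- allelic_gene_counts("gNull", "T1", c(0.65, 0.35), c(0.65, 0.35),
                                depth = 2000)
  div_g <- allelic_gene_counts("gDiv", "T1", c(0.65, 0.35), c(0.35, 0.65),
                               depth = 2000)
  af <- allelic_usage_with_filters(rbind(null_g, div_g))
  dv <- call_divergence(af)
  cn <- dv$calls[dv$calls$gene_id == "gNull", ]
  expect_true(all(cn$delta == 0))
  expect_false(any(cn$divergent))
  cd <- dv$calls[dv$calls$gene_id == "gDiv" & dv$calls$pas_id == "p1", ]
  expect_equal(cd$delta, 0.3, tolerance = 1e-9)
  expect_true(cd$divergent)
  expect_lt(cd$p_adj, 0.05)
  gd <- dv$genes[dv$genes$gene_id == "gDiv", ]
  expect_true(gd$divergent)
})

test_that("swapping allele channels flips every delta and nothing else", {
  set.seed(29)
  counts <- rbind(
    allelic_gene_counts("gA", "T1", c(0.7, 0.3), c(0.5, 0.5), 800),
    allelic_gene_counts("gB", "T1", c(0.4, 0.35, 0.25), c(0.5, 0.3, 0.2), 600))
  swapped <- transform(counts,
                       channel = ifelse(channel == "B6", "SPR",
                                        ifelse(channel == "SPR", "B6",
                                               channel)))
  a <- call_divergence(allelic_usage_with_filters(counts))
  b <- call_divergence(allelic_usage_with_filters(swapped))
  expect_equal(b$calls$delta, -a$calls$delta)
  expect_equal(b$calls$p_raw, a$calls$p_raw)
  expect_identical(b$calls$divergent, a$calls$divergent)
})

test_that("single-PAS genes are degenerate non-divergent calls", {
  counts <- allelic_gene_counts("gA", "T1", 1, 1, depth = 100, pas = "p1")
  dv <- call_divergence(allelic_usage_with_filters(counts))
  expect_true(dv$calls$degenerate)
  expect_equal(dv$calls$p_raw, 1)
  expect_false(dv$calls$divergent)
})

test_that("divergence classes partition by testable-tissue outcomes", {
  gc <- data.frame(
    gene_id = c(rep("all3", 3), rep("some3", 3), rep("non4", 4)),
    tissue = c(paste0("T", 1:3), paste0("T", 1:3), paste0("T", 1:4)),
    dominant_pas = "p1",
    divergent = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, rep(FALSE, 4)),
    stringsAsFactors = FALSE)
  cl <- classify_divergence(gc)
  expect_equal(cl$class[cl$gene_id == "all3"], "all_divergent")
  expect_equal(cl$class[cl$gene_id == "some3"], "some_divergent")
  expect_equal(cl$class[cl$gene_id == "non4"], "non_divergent")
  expect_equal(cl$n_testable_tissues[cl$gene_id == "non4"], 4L)
})

test_that("scaling-law table bins deltas and handles edge cases", {
  empty <- scaling_law_table(data.frame(usage_b6 = numeric(),
                                        delta = numeric()))
  expect_equal(nrow(empty$table), 0L)

  one_bin <- scaling_law_table(data.frame(usage_b6 = c(0.55, 0.57, 0.52),
                                          delta = c(0.1, 0.2, 0.15)))
  expect_equal(nrow(one_bin$tests), 0L)
  expect_equal(one_bin$table$n[1], 3L)
  expect_equal(one_bin$table$median_abs_delta[1], 0.15)

  two_bin <- scaling_law_table(data.frame(
    usage_b6 = c(0.55, 0.56, 0.57, 0.95, 0.96, 1.0),
    delta = c(0.3, 0.32, 0.31, 0.05, 0.04, 0.06)))
  expect_equal(sum(two_bin$table$n), 6L) # usage 1.0 lands in the last bin
  expect_equal(nrow(two_bin$tests), 1L)
  expect_lt(two_bin$table$median_abs_delta[5], two_bin$table$median_abs_delta[1])
})

test_that("variant density counts the strand-oriented inclusive window", {
  ann <- rbind(ann_gene("gA", 1000, pas = "a1"),
               ann_gene("gB", 5000, strand = "-", pas = "b1",
                        chrom = "chr2"))
  variants <- data.frame(
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr1", "chr2", "chr2"),
    pos = c(800, 900, 1100, 799, 1101, 5200, 4899))
  vd <- variant_density(variants, ann)
  # gA (+): window [800, 1100]; 799 and 1101 excluded
  expect_equal(vd$density$n_variants[vd$density$pas_id == "a1"], 3L)
  expect_equal(vd$density$density[vd$density$pas_id == "a1"], 3 / 301)
  # gB (-): upstream = larger coordinates, window [4900, 5200]
  expect_equal(vd$density$n_variants[vd$density$pas_id == "b1"], 1L)
  # profile offsets: 5200 on the minus strand is -200 (upstream)
  expect_equal(vd$profile$n_variants[vd$profile$offset == -200], 2L)
  expect_equal(sum(vd$profile$n_variants), 4L)
})

test_that("identical allele profiles merge first (r = 1)", {
  tissues <- paste0("T", 1:4)
  set.seed(31)
  base <- stats::setNames(stats::runif(8, 0.3, 0.9), paste0("g", 1:8))
  toff <- stats::setNames(seq(-0.1, 0.1, length.out = 4), tissues)
  fx <- cluster_fixture(8, tissues, function(g, t, al) base[g] + toff[t])
  cl <- allelic_clustering(fx, tissues = tissues)
  # columns T_B6 and T_SPR are identical: correlation exactly 1
  for (t in tissues) {
    expect_equal(cl$usage$cor[paste0(t, "_B6"), paste0(t, "_SPR")], 1)
  }
})

test_that("the dominant factor drives the top dendrogram split", {
  tissues <- paste0("T", 1:4)
  set.seed(37)
  base <- stats::setNames(stats::runif(20, 0.35, 0.65), paste0("g", 1:20))
  noise <- function() stats::rnorm(1, 0, 0.005)

  # allele effect dominates: gene-specific allelic shift, tiny tissue noise
  ashift <- stats::setNames(stats::runif(20, 0.15, 0.25), paste0("g", 1:20))
  fx_a <- cluster_fixture(20, tissues, function(g, t, al) {
    base[g] + (al == "B6") * ashift[g] + noise()
  })
  cl_a <- allelic_clustering(fx_a, tissues = tissues)
  grp <- stats::cutree(cl_a$usage$hclust, 2)
  al_lab <- sub("^.*_", "", names(grp))
  expect_true(all(tapply(grp, al_lab, function(x) length(unique(x)) == 1)))
  expect_equal(length(unique(grp[al_lab == "B6"])), 1L)
  expect_false(grp[al_lab == "B6"][1] == grp[al_lab == "SPR"][1])

  # tissue effect dominates: gene x tissue interaction shared by alleles
  tshift <- matrix(stats::runif(20 * 4, -0.2, 0.2), nrow = 20,
                   dimnames = list(paste0("g", 1:20), tissues))
  fx_t <- cluster_fixture(20, tissues, function(g, t, al) {
    base[g] + tshift[g, t] + noise()
  })
  cl_t <- allelic_clustering(fx_t, tissues = tissues)
  grp_t <- stats::cutree(cl_t$usage$hclust, 2)
  t_lab <- sub("_(B6|SPR)$", "", names(grp_t))
  # both alleles of any tissue land on the same side of the split
  expect_true(all(tapply(grp_t, t_lab, function(x) length(unique(x)) == 1)))
})

test_that("allelic expression divergence needs fold change and support", {
  strong <- rbind(
    cnt_row(paste0("T1_r", 1:3), "T1", 1:3, "gA", "p1", "B6", c(400, 410, 390)),
    cnt_row(paste0("T1_r", 1:3), "T1", 1:3, "gA", "p1", "SPR", c(100, 95, 105)))
  weak <- rbind(
    cnt_row(paste0("T1_r", 1:3), "T1", 1:3, "gB", "p1", "B6", c(110, 108, 112)),
    cnt_row(paste0("T1_r", 1:3), "T1", 1:3, "gB", "p1", "SPR", c(100, 102, 98)))
  res <- allelic_expression_divergence(rbind(strong, weak))
  expect_true(res$divergent[res$gene_id == "gA"])
  expect_false(res$divergent[res$gene_id == "gB"])
  expect_gt(res$log2_fold[res$gene_id == "gA"], 1)
})
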