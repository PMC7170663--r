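# Expression/usage quantification, dominant/major labels, down-sampling.

test_that("expression filter requires the threshold in every replicate", {
  counts <- rbind(
    gene_counts("gA", "T1", matrix(c(25, 25, 19), nrow = 1)),
    gene_counts("gB", "T1", matrix(c(20, 20, 20), nrow = 1)),
    gene_counts("gC", "T1", matrix(c(100, 100, 0), nrow = 1)))
  counts <- counts[counts$count > 0, ]
  ex <- filter_expressed_genes(counts)
  expect_false("gA" %in% ex$T1)
  expect_true("gB" %in% ex$T1)
  # gC has no row in replicate 3 at all
  expect_false("gC" %in% ex$T1)
})

test_that("used-PAS filter needs five reads in a single sample", {
  counts <- rbind(
    gene_counts("gA", "T1", matrix(c(4, 4, 4, 4, 4, 4), nrow = 2)),
    gene_counts("gB", "T1", matrix(c(5, 0, 0, 0, 0, 0), nrow = 2)))
  used <- filter_used_pas(counts)
  expect_false(any(used$gene_id == "gA"))
  expect_equal(used$pas_id[used$gene_id == "gB"], "p1")
})

test_that("usage vectors normalize within each scope", {
  counts <- gene_counts("gA", "T1", matrix(c(90, 10), nrow = 2))
  used <- data.frame(gene_id = "gA", pas_id = c("p1", "p2"))
  u <- compute_usage(counts, used, scope = "sample")
  expect_equal(u$usage, c(0.9, 0.1))

  counts2 <- gene_counts("gA", "T1", matrix(c(0, 50), nrow = 2))
  u2 <- compute_usage(counts2, used, scope = "sample")
  expect_equal(sort(u2$usage), c(0, 1))

  # replicates pooled before normalization: (10,10) + (30,50) -> (0.4, 0.6)
  counts3 <- gene_counts("gA", "T1", matrix(c(10, 10, 30, 50), nrow = 2))
  u3 <- compute_usage(counts3, used, scope = "tissue")
  expect_equal(u3$usage[u3$pas_id == "p1"], 0.4)
  expect_equal(u3$usage[u3$pas_id == "p2"], 0.6)
  expect_equal(unique(u3$total_reads), 100)
})

test_that("zero denominators yield no usage rows, never NaN", {
  counts <- rbind(gene_counts("gA", "T1", matrix(c(10, 10), nrow = 2)),
                  gene_counts("gA", "T2", matrix(c(0, 0), nrow = 2)))
  used <- data.frame(gene_id = "gA", pas_id = c("p1", "p2"))
  u <- compute_usage(counts, used, scope = "tissue")
  expect_equal(unique(u$tissue), "T1")
  expect_false(any(is.nan(u$usage)))
})

test_that("allelic usage scope uses only allele channels", {
  counts <- rbind(
    gene_counts("gA", "T1", matrix(c(60, 40), nrow = 2), channel = "B6"),
    gene_counts("gA", "T1", matrix(c(20, 80), nrow = 2), channel = "SPR"),
    gene_counts("gA", "T1", matrix(c(500, 500), nrow = 2), channel = "common"))
  used <- data.frame(gene_id = "gA", pas_id = c("p1", "p2"))
  u <- compute_usage(counts, used, scope = "tissue_allele")
  expect_equal(u$usage[u$allele == "B6" & u$pas_id == "p1"], 0.6)
  expect_equal(u$usage[u$allele == "SPR" & u$pas_id == "p1"], 0.2)
})

test_that("RPM satisfies the exact conservation identity", {
  d <- simulate_apa_dataset(sim_config(n_genes = 25, tissues = c("A", "B"),
                                       seed = 8))
  expr <- compute_expression(d$counts)
  tot <- expr$sample_totals
  for (s in tot$sample) {
    rpm <- expr$sample_rpm$rpm[expr$sample_rpm$sample == s]
    t <- tot$total[tot$sample == s]
    expect_equal(sum(rpm * t / 1e6), t, tolerance = 1e-12)
  }
})

test_that("dominant and major PAS labels follow the usage means", {
  # T1 (0.6, 0.4), T2 (0.2, 0.8): dominant p1/T1, p2/T2; major p2 (mean 0.6)
  counts <- rbind(gene_counts("gA", "T1", matrix(c(60, 40), nrow = 2)),
                  gene_counts("gA", "T2", matrix(c(20, 80), nrow = 2)))
  ann <- ann_gene("gA", c(100, 200))
  used <- data.frame(gene_id = "gA", pas_id = c("p1", "p2"))
  u <- compute_usage(counts, used, scope = "tissue")
  ex <- list(T1 = "gA", T2 = "gA")
  dm <- dominant_and_major_pas(u, ex, ann)
  expect_equal(dm$dominant$dominant_pas[dm$dominant$tissue == "T1"], "p1")
  expect_equal(dm$dominant$dominant_pas[dm$dominant$tissue == "T2"], "p2")
  expect_equal(dm$genes$major_pas, "p2")
  expect_equal(dm$genes$major_usage, 0.6)
  expect_equal(dm$genes$pas_class, "multi")
})

test_that("usage ties break to the smaller cleavage coordinate", {
  counts <- gene_counts("gA", "T1", matrix(c(50, 50), nrow = 2))
  ann <- ann_gene("gA", c(500, 300), pas = c("p1", "p2"))
  used <- data.frame(gene_id = "gA", pas_id = c("p1", "p2"))
  u <- compute_usage(counts, used, scope = "tissue")
  dm <- dominant_and_major_pas(u, list(T1 = "gA"), ann)
  # p2 sits at coordinate 300 < 500
  expect_equal(dm$dominant$dominant_pas, "p2")
  expect_equal(dm$genes$major_pas, "p2")
})

test_that("single-PAS genes and major-PAS location classes are derived", {
  counts <- rbind(gene_counts("gA", "T1", matrix(c(30), nrow = 1)),
                  gene_counts("gB", "T1",
                              matrix(c(10, 50, 20), nrow = 3),
                              pas = c("q1", "q2", "q3")))
  ann <- rbind(ann_gene("gA", 100),
               ann_gene("gB", c(1000, 1500, 2000), pas = c("q1", "q2", "q3")))
  used <- data.frame(gene_id = c("gA", "gB", "gB", "gB"),
                     pas_id = c("p1", "q1", "q2", "q3"))
  u <- compute_usage(counts, used, scope = "tissue")
  dm <- dominant_and_major_pas(u, list(T1 = c("gA", "gB")), ann)
  gA <- dm$genes[dm$genes$gene_id == "gA", ]
  expect_equal(gA$pas_class, "single")
  expect_equal(gA$major_location, "utr3_S")
  gB <- dm$genes[dm$genes$gene_id == "gB", ]
  expect_equal(gB$pas_class, "multi")
  expect_equal(gB$major_pas, "q2") # middle of three UTR PASs
  expect_equal(gB$major_location, "utr3_M")
})

test_that("location classes respect the minus strand", {
  # minus strand: largest coordinate is transcriptionally first (proximal)
  ann <- ann_gene("gC", c(1000, 1500, 2000), strand = "-",
                  pas = c("r1", "r2", "r3"))
  expect_equal(ann$utr_rank[ann$cleavage_pos == 2000], 1L)
  counts <- gene_counts("gC", "T1", matrix(c(70, 10, 20), nrow = 3),
                        pas = c("r1", "r2", "r3"))
  used <- data.frame(gene_id = "gC", pas_id = c("r1", "r2", "r3"))
  u <- compute_usage(counts, used, scope = "tissue")
  dm <- dominant_and_major_pas(u, list(T1 = "gC"), ann)
  # r1 at coordinate 1000 is the most distal on the minus strand
  expect_equal(dm$genes$major_pas, "r1")
  expect_equal(dm$genes$major_location, "utr3_L")
})

test_that("exactly-three-UTR-PAS rule applies its strict boundary", {
  ann <- rbind(
    ann_gene("gA", c(100, 200, 300, 400),
             region = c("upstream", "utr3", "utr3", "utr3")),
    ann_gene("gB", c(100, 200, 300, 400),
             region = c("upstream", "utr3", "utr3", "utr3"),
             pas = paste0("q", 1:4)),
    ann_gene("gC", c(100, 200, 300, 400), pas = paste0("r", 1:4)))
  used <- data.frame(
    gene_id = rep(c("gA", "gB", "gC"), each = 4),
    pas_id = c(paste0("p", 1:4), paste0("q", 1:4), paste0("r", 1:4)))
  counts <- rbind(
    # gA: UTR usage sum exactly 0.5 -> excluded (strict >)
    gene_counts("gA", "T1", matrix(c(50, 20, 20, 10), nrow = 4)),
    # gB: UTR sum 0.9 -> included
    gene_counts("gB", "T1", matrix(c(10, 40, 30, 20), nrow = 4),
                pas = paste0("q", 1:4)),
    # gC: four used UTR PASs -> excluded
    gene_counts("gC", "T1", matrix(c(25, 25, 25, 25), nrow = 4),
                pas = paste0("r", 1:4)))
  u <- compute_usage(counts, used, scope = "tissue")
  sel <- select_exactly_three_utr_pas_genes(
    u, ann, list(T1 = c("gA", "gB", "gC")))
  expect_equal(sel, "gB")
})

test_that("down-sampling draws without replacement at equal depth", {
  one <- gene_counts("gA", "T1", matrix(c(500, 500), nrow = 1))
  ds <- downsample_counts(one, n = 100, seed = 1)
  expect_equal(ds$count, 100L)

  small <- gene_counts("gB", "T1", matrix(c(40, 40), nrow = 1))
  ds2 <- downsample_counts(small, n = 100, seed = 1)
  expect_equal(attr(ds2, "skipped"), "gB")
  expect_error(downsample_counts(one, n = 0), "positive")
})

test_that("down-sampled counts follow the hypergeometric distribution", {
  # one sample, pooled (900, 100): no depth rescaling, pure hypergeometric
  counts <- gene_counts("gA", "T1", matrix(c(900, 100), nrow = 2))
  draws <- vapply(1:200, function(i) {
    ds <- downsample_counts(counts, n = 100, seed = i)
    ds$count[ds$pas_id == "p1"]
  }, 0L)
  lo <- qhyper(0.005, 900, 100, 100)
  hi <- qhyper(0.995, 900, 100, 100)
  # the central 99% interval may miss ~1% of draws
  expect_lte(mean(draws < lo | draws > hi), 0.03)
  expect_lt(abs(mean(draws) - 90), 1.5) # mean 90, se ~ 0.2
})

test_that("down-sampled usage converges to full-data usage with depth", {
  d <- simulate_apa_dataset(sim_config(n_genes = 40, tissues = c("A", "B"),
                                       libsize_mean = 3000, seed = 33))
  pooled <- rowsum(d$counts$count,
                   paste(d$counts$gene_id, d$counts$pas_id, sep = "\r"))
  parts <- do.call(rbind, strsplit(rownames(pooled), "\r", fixed = TRUE))
  full <- data.frame(gene_id = parts[, 1], pas_id = parts[, 2],
                     count = pooled[, 1])
  gene_tot <- tapply(full$count, full$gene_id, sum)
  full$usage <- full$count / gene_tot[full$gene_id]
  mae <- vapply(c(10, 50, 100, 500), function(n) {
    ds <- downsample_counts(d$counts, n = n, seed = 55)
    ds_tot <- tapply(ds$count, ds$gene_id, sum)
    ds$usage <- ds$count / ds_tot[ds$gene_id]
    key <- paste(full$gene_id, full$pas_id)
    dsu <- ds$usage[match(key, paste(ds$gene_id, ds$pas_id))]
    keep <- full$gene_id %in% ds$gene_id
    mean(abs(dsu[keep] - full$usage[keep]), na.rm = TRUE)
  }, 0)
  expect_true(all(diff(mae) < 0))
})
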