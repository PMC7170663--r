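# Functional gene groups, switched flags, high-confidence support.

mk_dominant <- function(gene, tissues, dom_u, r2_u) {
  data.frame(gene_id = gene, tissue = tissues, dominant_pas = "p1",
             dominant_usage = dom_u, rank2_pas = "p2", rank2_usage = r2_u,
             stringsAsFactors = FALSE)
}

mk_info <- function(genes, cls = "multi") {
  data.frame(gene_id = genes, pas_class = cls, major_pas = "p1",
             major_usage = 0.5, major_location = "utr3_F", n_used_pas = 2L,
             n_expressing_tissues = 2L, stringsAsFactors = FALSE)
}

test_that("F1/F2/FU assignment follows the usage thresholds", {
  dom <- rbind(
    mk_dominant("f1gene", c("T1", "T2"), c(0.95, 0.96), c(0.05, 0.04)),
    mk_dominant("f2gene", c("T1", "T2"), c(0.55, 0.80), c(0.45, 0.20)),
    mk_dominant("fugene", c("T1", "T2"), c(0.85, 0.85), c(0.10, 0.10)))
  g <- classify_f1_f2_fu(dom, mk_info(c("f1gene", "f2gene", "fugene")))
  expect_equal(g$group[g$gene_id == "f1gene"], "F1")
  expect_equal(g$group[g$gene_id == "f2gene"], "F2")
  expect_equal(g$group[g$gene_id == "fugene"], "FU")
  expect_equal(g$f2_tissues[g$gene_id == "f2gene"], "T1")
})

test_that("F1 and F2 boundaries are inclusive", {
  dom <- rbind(mk_dominant("gA", "T1", 0.90, 0.10),   # exactly 0.90 -> F1
               mk_dominant("gB", "T1", 0.60, 0.40),   # gap exactly 0.20 -> F2
               mk_dominant("gC", "T1", 0.899, 0.10))  # fails both -> FU
  g <- classify_f1_f2_fu(dom, mk_info(c("gA", "gB", "gC")))
  expect_equal(g$group, c("F1", "F2", "FU"))
})

test_that("single-PAS genes never enter the groups; partition is exact", {
  d <- simulate_apa_dataset(sim_config(n_genes = 60, seed = 3))
  rep1 <- run_pipeline(d$counts, d$annotations, n_mock = 20, seed = 3)
  cl <- rep1$classification
  multi <- rep1$gene_info$gene_id[rep1$gene_info$pas_class == "multi"]
  expect_setequal(cl$gene_id, multi)
  expect_true(all(cl$group %in% c("F1", "F2", "FU")))
  expect_false(any(duplicated(cl$gene_id)))
})

test_that("switched flag applies the inclusive 0.5 threshold", {
  sw <- data.frame(gene_id = c("a", "b", "c"),
                   switch_score = c(0.50, 0.49, NA))
  fl <- flag_switched(sw)
  expect_identical(unname(fl), c(TRUE, FALSE, FALSE))
})

# builds the inputs of functional_and_high_confidence for one F2 gene whose
# secondary usage and expression vary across five tissues
hc_setup <- function(rpm, sec_usage) {
  tissues <- paste0("T", seq_along(rpm))
  groups <- data.frame(gene_id = "g1", group = "F2",
                       f2_tissues = tissues[1], f2_pas = "p2",
                       stringsAsFactors = FALSE)
  usage_tissue <- data.frame(
    gene_id = "g1", tissue = rep(tissues, each = 2),
    pas_id = rep(c("p1", "p2"), length(rpm)),
    usage = as.vector(rbind(1 - sec_usage, sec_usage)),
    total_reads = 1000, stringsAsFactors = FALSE)
  # five filler genes define the per-tissue median RPM (all at RPM 500)
  fillers <- paste0("f", 1:5)
  tiss_rpm <- rbind(
    data.frame(gene_id = "g1", tissue = tissues, rpm = rpm),
    expand.grid(gene_id = fillers, tissue = tissues,
                stringsAsFactors = FALSE)[, 1:2] |>
      transform(rpm = 500))
  expressed <- stats::setNames(lapply(tissues, function(t) c("g1", fillers)),
                               tissues)
  list(groups = groups, usage = usage_tissue,
       expression = list(tissue_rpm = tiss_rpm), expressed = expressed,
       switch_table = data.frame(gene_id = "g1", tissue_a = "T1",
                                 tissue_b = "T2", stringsAsFactors = FALSE))
}

test_that("high-confidence correlation arm matches the exact Spearman p", {
  # monotone coupling over n = 5 tissues: exact two-sided p = 1/60 < 0.05
  s <- hc_setup(rpm = c(10, 20, 30, 40, 50),
                sec_usage = c(0.30, 0.32, 0.34, 0.36, 0.38))
  fun <- functional_and_high_confidence(s$groups, c(g1 = FALSE), s$usage,
                                        s$expression, s$expressed,
                                        s$switch_table)
  expect_true(fun$functional_type)
  expect_true(fun$high_confidence)
  expect_equal(fun$hc_arm, "correlation")

  # brute-force permutation oracle for the exact two-sided p of rho = 1, n = 5
  perms <- combinat_perms(5)
  rhos <- apply(perms, 1, function(pp) stats::cor(1:5, pp, method = "spearman"))
  p_exact <- mean(abs(rhos) >= 1 - 1e-12)
  expect_equal(p_exact, 1 / 60)
  ct <- stats::cor.test(1:5, 1:5, method = "spearman")
  expect_equal(ct$p.value, p_exact, tolerance = 1e-12)
})

test_that("low-expression anticorrelated F2 genes are not high-confidence", {
  s <- hc_setup(rpm = c(10, 20, 30, 40, 50),
                sec_usage = c(0.38, 0.36, 0.34, 0.32, 0.30))
  fun <- functional_and_high_confidence(s$groups, c(g1 = FALSE), s$usage,
                                        s$expression, s$expressed,
                                        s$switch_table)
  expect_true(fun$functional_type)
  expect_false(fun$high_confidence) # rho < 0 and RPM below the 500 median
})

test_that("median arm rescues high-expression genes without correlation", {
  s <- hc_setup(rpm = c(900, 20, 30, 40, 10),
                sec_usage = c(0.38, 0.36, 0.34, 0.32, 0.30))
  # secondary usage peaks in T1 where RPM 900 > median 500
  fun <- functional_and_high_confidence(s$groups, c(g1 = FALSE), s$usage,
                                        s$expression, s$expressed,
                                        s$switch_table)
  expect_true(fun$high_confidence)
  expect_equal(fun$hc_arm, "median")
})

test_that("functional type is the union of F2 and switched FU genes", {
  groups <- data.frame(gene_id = c("a", "b", "c"),
                       group = c("F2", "FU", "FU"),
                       f2_tissues = c("T1", NA, NA),
                       f2_pas = c("p2", NA, NA), stringsAsFactors = FALSE)
  usage <- data.frame(gene_id = character(), tissue = character(),
                      pas_id = character(), usage = numeric(),
                      total_reads = numeric(), stringsAsFactors = FALSE)
  expr <- list(tissue_rpm = data.frame(gene_id = character(),
                                       tissue = character(), rpm = numeric(),
                                       stringsAsFactors = FALSE))
  sw_tab <- data.frame(gene_id = c("a", "b", "c"), tissue_a = "T1",
                       tissue_b = "T2", stringsAsFactors = FALSE)
  fun <- functional_and_high_confidence(
    groups, c(a = FALSE, b = TRUE, c = FALSE), usage, expr,
    list(T1 = character(), T2 = character()), sw_tab)
  expect_identical(fun$functional_type, c(TRUE, TRUE, FALSE))
  # invariant: high confidence implies functional type
  expect_true(all(!fun$high_confidence | fun$functional_type))
})

test_that("brain-specific flag requires exclusively brain F2 hits", {
  groups <- data.frame(
    gene_id = c("a", "b", "c", "d"),
    group = "F2",
    f2_tissues = c("COR", "COR,LIV", "CER,COR", NA),
    f2_pas = "p2", stringsAsFactors = FALSE)
  fl <- flag_brain_specific_f2(groups)
  expect_identical(unname(fl), c(TRUE, FALSE, TRUE, FALSE))
})

test_that("classification is invariant to row order and PAS relabelling", {
  d <- simulate_apa_dataset(sim_config(n_genes = 40, seed = 47))
  rep1 <- run_pipeline(d$counts, d$annotations, n_mock = 20, seed = 47)
  base <- rep1$classification[order(rep1$classification$gene_id), ]

  # shuffle input row order
  cc <- d$counts[sample(nrow(d$counts)), ]
  rep2 <- run_pipeline(cc, d$annotations, n_mock = 20, seed = 47)
  shuf <- rep2$classification[order(rep2$classification$gene_id), ]
  expect_equal(shuf$group, base$group)
  expect_equal(shuf$switched, base$switched)

  # relabel PASs consistently (keeps lexicographic order within genes)
  relab <- function(x) sub(":PAS", ":Q", x, fixed = TRUE)
  cc2 <- transform(d$counts, pas_id = relab(pas_id))
  ann2 <- transform(d$annotations, pas_id = relab(pas_id))
  rep3 <- run_pipeline(cc2, ann2, n_mock = 20, seed = 47)
  rl <- rep3$classification[order(rep3$classification$gene_id), ]
  expect_equal(rl$group, base$group)
  expect_equal(rl$switched, base$switched)
})
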