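# Normalized z-score CRISPR essentiality method.

crispr_toy <- function() {
  # 4 genes x 4 sgRNAs + 2 control pseudo-genes x 4, one replicate per
  # condition, counts small enough to hand-check
  genes <- paste0("G", 1:4)
  ctrl <- paste0("NC", 1:2)
  lib <- data.frame(
    element_id = c(paste0(rep(genes, each = 4), "_sg", 1:4),
                   paste0(rep(ctrl, each = 4), "_sg", 1:4)),
    gene = c(rep(genes, each = 4), rep(ctrl, each = 4)),
    class = rep(c("targeting", "control_noncutting"), c(16, 8)),
    stringsAsFactors = FALSE)
  set.seed(99)
  pre <- rpois(24, 500) + 100L
  post <- pre
  post[1:4] <- round(pre[1:4] / 16)       # G1 depleted 2^-4
  post[5:8] <- round(pre[5:8] / 2)        # G2 depleted 2^-1
  counts <- cbind(pre = pre, screen = post)
  rownames(counts) <- lib$element_id
  m <- count_matrix(counts, data.frame(
    sample_id = c("pre", "screen"),
    condition = c("pre_swap", "uridine"),
    replicate = 1L, day = c(0, 21),
    role = c("pre_swap_reference", "screen")))
  list(m = m, lib = lib, genes = genes, ctrl = ctrl)
}

test_that("gene-level LFC averages its sgRNAs and keeps control pseudo-genes", {
  toy <- crispr_toy()
  norm <- normalize_log2_rpm(toy$m)
  gl <- gene_level_lfc(norm, toy$lib, "pre", "screen")
  expect_setequal(gl$gene, c(toy$genes, toy$ctrl))
  expect_equal(unique(gl$n_elements), 4L)
  # independent spreadsheet-style recomputation
  man_norm <- apply(toy$m$counts, 2, function(x) log2(x / sum(x) * 1e6 + 1))
  man_lfc <- man_norm[, "screen"] - man_norm[, "pre"]
  for (g in c(toy$genes, toy$ctrl)) {
    els <- toy$lib$element_id[toy$lib$gene == g]
    expect_equal(gl$lfc[gl$gene == g], mean(man_lfc[els]), tolerance = 1e-12)
  }
  expect_equal(unique(gl$class[gl$gene %in% toy$ctrl]), "control_noncutting")
})

test_that("simple sgRNA LFC patterns average as expected", {
  # {-1,-1,-1,-1} -> -1 and {0,0,-2,-2} -> -1, built from exact counts
  pre <- rep(1000, 8)
  post <- c(rep(500, 4), 1000, 1000, 250, 250)
  counts <- cbind(pre = pre, screen = post)
  rownames(counts) <- paste0(rep(c("A", "B"), each = 4), "_sg", 1:4)
  filler <- rbind(fill_sg = c(1e6 - sum(pre), 1e6 - sum(post)))
  counts <- rbind(counts, filler)  # fix totals at 1e6 so RPM == reads
  lib <- data.frame(element_id = rownames(counts),
                    gene = c(rep(c("A", "B"), each = 4), "FILL"),
                    class = "targeting")
  m <- count_matrix(counts, data.frame(
    sample_id = c("pre", "screen"), condition = c("pre_swap", "uridine"),
    replicate = 1L, day = c(0, 21),
    role = c("pre_swap_reference", "screen")))
  gl <- gene_level_lfc(normalize_log2_rpm(m), lib, "pre", "screen")
  # pseudocount shifts log2(501/1001) etc. slightly off -1
  expect_equal(gl$lfc[gl$gene == "A"], log2(501 / 1001), tolerance = 1e-12)
  expect_equal(gl$lfc[gl$gene == "B"],
               mean(c(0, 0, log2(251 / 1001), log2(251 / 1001))),
               tolerance = 1e-12)
  expect_error(gene_level_lfc(normalize_log2_rpm(m), lib, "screen", "pre"),
               "pre_swap_reference")
})

test_that("expression filter removes strictly sub-threshold and unknown genes", {
  expr <- data.frame(gene = c("A", "B", "C"), log2_fpkm = c(-0.1, 0, 2.5))
  expect_equal(filter_expressed(c("A", "B", "C", "D"), expr), c("B", "C"))
  expect_equal(filter_expressed(c("A", "C"), expr, threshold = 3), character())
})

test_that("null model statistics and tie-breaking follow the contract", {
  lfcs <- setNames(c(rep(0.5, 9), 1.5), paste0("g", 1:10))
  expr <- data.frame(gene = paste0("g", 1:10), log2_fpkm = rep(-1, 10))
  null <- build_null(lfcs, expr, k = 10)
  expect_equal(null$mu, mean(c(rep(0.5, 9), 1.5)))
  expect_equal(null$sigma, sd(c(rep(0.5, 9), 1.5)))
  expect_equal(null$k, 10)

  # ties at the k-th rank resolve lexicographically by gene id
  expr2 <- data.frame(gene = c("zz", "aa", "mm"), log2_fpkm = c(-2, -1, -1))
  lfcs2 <- setNames(c(1, 2, 3), c("zz", "aa", "mm"))
  null2 <- build_null(lfcs2, expr2, k = 2)
  expect_setequal(null2$member_genes, c("zz", "aa"))

  expect_error(build_null(lfcs, expr, k = 1), "k >= 2")
  expect_error(build_null(lfcs, expr, k = 11), "exceeds")
  const <- setNames(rep(1, 5), paste0("g", 1:5))
  expect_error(build_null(const, expr[1:5, ], k = 5), "degenerate null")
})

test_that("z-scoring is exact arithmetic against the null statistics", {
  null <- build_null(setNames(c(-1, 0, 1), c("a", "b", "c")),
                     data.frame(gene = c("a", "b", "c"),
                                log2_fpkm = c(-3, -2, -1)), k = 3)
  expect_equal(null$mu, 0)
  expect_equal(null$sigma, 1)
  z <- zscore_genes(setNames(c(0, 2), c("x", "y")), null)
  expect_equal(unname(z), c(0, 2))
})

test_that("null members z-score to mean 0 and sample sd 1 under both modes", {
  sim <- simulate_crispr_screen(n_genes = 300,
                                planted = list(specific = 20), seed = 4)
  for (mode in c("expression", "noncutting")) {
    sc <- score_crispr_condition(sim$counts, sim$library, sim$expression,
                                 "uridine", null_mode = mode)
    members <- setNames(sc$gene_lfcs$lfc, sc$gene_lfcs$gene)[sc$null$member_genes]
    z <- zscore_genes(members, sc$null)
    expect_lt(abs(mean(z)), 1e-12)
    expect_lt(abs(sd(z) - 1), 1e-12)
  }
})

test_that("z-scores are equivariant under shifting and scaling of LFCs", {
  set.seed(21)
  lfcs <- setNames(rnorm(50), paste0("g", 1:50))
  expr <- data.frame(gene = names(lfcs), log2_fpkm = runif(50, -3, 3))
  null <- build_null(lfcs, expr, k = 10)
  z0 <- zscore_genes(lfcs, null)
  # shift: z moves by c / sigma
  null_s <- build_null(lfcs + 5, expr, k = 10)
  expect_equal(zscore_genes(lfcs + 5, null_s), z0, tolerance = 1e-9)
  expect_equal(zscore_genes(lfcs + 5, null) - z0,
               rep(5 / null$sigma, 50), ignore_attr = TRUE)
  # scale: mu and sigma rescale, null-member z unchanged
  null_m <- build_null(lfcs * 3, expr, k = 10)
  expect_equal(null_m$mu, 3 * null$mu)
  expect_equal(null_m$sigma, 3 * null$sigma)
  expect_equal(zscore_genes(lfcs * 3, null_m), z0, tolerance = 1e-9)
})

test_that("end-to-end toy screen matches a spreadsheet-style hand computation", {
  toy <- crispr_toy()
  expr <- data.frame(gene = toy$genes, log2_fpkm = c(5, 4, -1, -2))
  sc <- score_crispr_condition(toy$m, toy$lib, expr, "uridine",
                               null_mode = "noncutting")
  # hand path: normalize, per-sgRNA LFC, gene means, z vs control stats
  man_norm <- apply(toy$m$counts, 2, function(x) log2(x / sum(x) * 1e6 + 1))
  man_lfc <- man_norm[, "screen"] - man_norm[, "pre"]
  gmean <- tapply(man_lfc, toy$lib$gene, mean)
  mu <- mean(gmean[toy$ctrl]); sigma <- sd(gmean[toy$ctrl])
  expect_setequal(sc$scores$gene, c("G1", "G2"))  # G3, G4 filtered (expr < 0)
  for (g in c("G1", "G2"))
    expect_equal(sc$scores$z[sc$scores$gene == g],
                 unname((gmean[g] - mu) / sigma), tolerance = 1e-12)
  expect_lt(sc$scores$z[sc$scores$gene == "G1"],
            sc$scores$z[sc$scores$gene == "G2"])
})

test_that("differential essentiality classifies by the documented conventions", {
  z_glu <- setNames(c(0, -0.2, -6, -4), c("n", "pgm2", "shared", "gluonly"))
  z_u <- setNames(c(0, -6, -5, -0.5), c("n", "pgm2", "shared", "gluonly"))
  d <- differential_essentiality(z_glu, z_u, labels = c("glu", "u"))
  cls <- setNames(d$class, d$gene)
  expect_equal(cls[["n"]], "neutral")
  expect_equal(cls[["pgm2"]], "u_specific_essential")
  expect_equal(cls[["shared"]], "shared_essential")
  expect_equal(cls[["gluonly"]], "glu_specific_essential")
  expect_equal(d$dz, unname(z_u[d$gene] - z_glu[d$gene]))
})

test_that("planted condition-specific essentials are recovered by dz ranking", {
  sim <- simulate_crispr_screen(n_genes = 500, planted = list(specific = 25),
                                effect_log2 = -4, seed = 2)
  sg <- score_crispr_condition(sim$counts, sim$library, sim$expression,
                               "glucose")
  su <- score_crispr_condition(sim$counts, sim$library, sim$expression,
                               "uridine")
  d <- differential_essentiality(setNames(sg$scores$z, sg$scores$gene),
                                 setNames(su$scores$z, su$scores$gene),
                                 labels = c("glu", "u"))
  truth <- sim$truth$planted_specific[match(d$gene, sim$truth$gene)]
  expect_gte(auroc(-d$dz, truth), 0.95)
})
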