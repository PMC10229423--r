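# Multiplexed barcoded cell-line growth analysis.

prism_toy <- function() {
  data.frame(
    cell_line = rep(c("L1", "L2", "L3"), each = 3),
    lineage = rep(c("mel", "mel", "ewing"), each = 3),
    replicate = rep(1:3, 3),
    n_g = c(500, 480, 3, 100, 100, 100, 800, 800, 800),
    n_u = c(1000, 960, 980, 100, 100, 100, 100, 100, 100),
    n_0 = rep(c(200, 100, 1), each = 3))
}

test_that("closed-form metrics are exact on power-of-two grids", {
  expect_equal(prism_lfc(200, 100), 1)
  expect_equal(prism_lfc(100, 800), -3)
  expect_equal(prism_lfc(100, 100), 0)
  expect_equal(growth_rate(1, 64, 6), 1)
  expect_equal(growth_rate(100, 100, 6), 0)
  grid <- expand.grid(a = 2^(0:10), b = 2^(0:10))
  expect_equal(prism_lfc(grid$a, grid$b), log2(grid$a) - log2(grid$b))
  expect_equal(growth_rate(grid$b, grid$a, t = 2),
               (log2(grid$a) - log2(grid$b)) / 2)
  expect_error(growth_rate(1, 64, 0), "positive")
})

test_that("zero or missing counts give missing metrics, never infinities", {
  expect_true(is.na(prism_lfc(0, 100)))
  expect_true(is.na(prism_lfc(100, NA)))
  expect_true(is.na(growth_rate(0, 5, 6)))
})

test_that("low-count filter masks replicates and collapse averages the rest", {
  rec <- prism_toy()
  f <- filter_low_counts(rec, floor = 20)
  expect_true(is.na(f$n_g[3]))                 # the 3-read replicate
  expect_equal(sum(is.na(f$n_g)), 1)
  col <- collapse_replicates(f)
  expect_equal(col$n_g[col$cell_line == "L1"], mean(c(500, 480)))
  expect_equal(col$n_u[col$cell_line == "L1"], mean(c(1000, 960, 980)))
  # floor 0 leaves everything untouched
  expect_equal(filter_low_counts(rec, 0), rec)
  # all replicates masked in one condition -> missing metric, message
  rec2 <- prism_toy()
  rec2$n_g[rec2$cell_line == "L1"] <- c(5, 8, 3)
  expect_message(col2 <- collapse_replicates(filter_low_counts(rec2, 20)),
                 "all replicates masked")
  expect_true(is.na(col2$n_g[col2$cell_line == "L1"]))
  mt2 <- suppressMessages(prism_metrics(rec2))
  expect_true(is.na(mt2$lfc[mt2$cell_line == "L1"]))
})

test_that("per-line metrics match hand computation on the 3-line toy", {
  mt <- prism_metrics(prism_toy(), floor = 20, t_days = 6)
  expect_equal(mt$lfc[mt$cell_line == "L1"],
               log2(mean(c(1000, 960, 980)) / mean(c(500, 480))))
  expect_equal(mt$lfc[mt$cell_line == "L2"], 0)
  expect_equal(mt$lfc[mt$cell_line == "L3"], -3)
  expect_equal(mt$growth_rate_glu[mt$cell_line == "L3"], log2(800 / 1) / 6)
  expect_equal(mt$growth_rate_uri[mt$cell_line == "L2"], 0)
})

test_that("lineage enrichment flags tiny lineages and orders q by p", {
  set.seed(5)
  metrics <- data.frame(
    cell_line = paste0("L", 1:41),
    lineage = c(rep("big_up", 10), rep("big_null", 15), rep("mid", 15),
                "singleton"),
    lfc = c(rnorm(10, 2, 0.3), rnorm(15, 0, 0.3), rnorm(15, 0, 0.3),
            rnorm(1)))
  enr <- lineage_enrichment(metrics)
  single <- enr[enr$lineage == "singleton", ]
  expect_false(single$tested)
  expect_true(is.na(single$p))
  expect_equal(enr$lineage[1], "big_up")
  expect_gt(enr$effect[1], 1.5)
  tested <- enr[enr$tested, ]
  expect_equal(tested$q, benjamini_hochberg(tested$p))
  expect_true(all(diff(tested$q[order(tested$p)]) >= -1e-15))
  expect_error(lineage_enrichment(data.frame(lineage = "a", lfc = 1)),
               ">= 2 lineages")
})

test_that("a planted lineage shift is detected as the smallest q", {
  sim <- simulate_prism(n_lines = 220, lineage_shift = 2, n_features = 0,
                        seed = 8)
  enr <- lineage_enrichment(prism_metrics(sim$records))
  expect_equal(enr$lineage[which.min(enr$q)], sim$truth$planted_lineage)
})

test_that("planted-free runs rarely produce a significant lineage", {
  ok <- 0
  for (s in 1:100) {
    sim <- simulate_prism(n_lines = 220, lineage_shift = 0, n_features = 0,
                          seed = s)
    enr <- lineage_enrichment(prism_metrics(sim$records))
    if (min(enr$q, na.rm = TRUE) >= 0.05) ok <- ok + 1
  }
  expect_gte(ok, 90)
})

test_that("biomarker correlation identities hold and BH is within class", {
  set.seed(12)
  n <- 30
  lfc <- rnorm(n)
  lines <- paste0("L", 1:n)
  metrics <- data.frame(cell_line = lines, lineage = "x", lfc = lfc)
  feats <- cbind(self = lfc, anti = -lfc, noise = rnorm(n), const = 1)
  rownames(feats) <- lines
  expect_warning(
    bc <- biomarker_correlation(metrics, feats,
                                feature_class = c("t", "t", "p", "p")),
    "constant feature")
  expect_equal(bc$feature[1:2], c("anti", "self"))  # |r| ties, alphabetical
  expect_equal(bc$r[bc$feature == "self"], 1)
  expect_equal(bc$r[bc$feature == "anti"], -1)
  expect_false("const" %in% bc$feature)
  for (cl in c("t", "p")) {
    sel <- bc$feature_class == cl
    expect_equal(sort(bc$q[sel]), sort(benjamini_hochberg(bc$p[sel])))
  }
})

test_that("correlation p-values match cor.test feature by feature", {
  set.seed(31)
  n <- 25
  lfc <- rnorm(n)
  feats <- matrix(rnorm(n * 5), n, 5,
                  dimnames = list(paste0("L", 1:n), paste0("F", 1:5)))
  feats[sample(length(feats), 10)] <- NA  # exercise pairwise handling
  metrics <- data.frame(cell_line = rownames(feats), lineage = "x", lfc = lfc)
  bc <- biomarker_correlation(metrics, feats)
  for (f in bc$feature) {
    keep <- !is.na(feats[, f])
    ref <- cor.test(feats[keep, f], lfc[keep])
    i <- match(f, bc$feature)
    expect_equal(bc$r[i], unname(ref$estimate), tolerance = 1e-12)
    expect_equal(bc$p[i], ref$p.value, tolerance = 1e-12)
  }
})

test_that("permuting line order changes nothing; permuting lfc kills the signal", {
  sim <- simulate_prism(n_lines = 120, n_features = 300, r_true = 0.6,
                        seed = 6)
  mt <- prism_metrics(sim$records)
  bc <- biomarker_correlation(mt, sim$features, "transcript")
  perm <- sample(nrow(mt))
  bc2 <- biomarker_correlation(mt[perm, ], sim$features, "transcript")
  expect_equal(bc2, bc)
  expect_equal(bc$feature[1], sim$truth$planted_feature)
  # permute lfc against features: planted correlation collapses to null scale
  set.seed(77)
  rs <- replicate(20, {
    mtp <- mt; mtp$lfc <- sample(mtp$lfc)
    bcp <- biomarker_correlation(mtp, sim$features, "transcript")
    abs(bcp$r[bcp$feature == sim$truth$planted_feature])
  })
  expect_lt(mean(rs), 0.2)
})
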