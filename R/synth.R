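## Synthetic screens with planted ground truth. All generators are pure
## functions of (parameters, seed): one master seed deterministically
## derives an independent substream per generation stage.

stream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, seed == round(seed))
  as.integer((abs(seed) * 1009L + stream * 7919L) %% .Machine$integer.max)
}

with_stream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(stream_seed(seed, stream))
  expr
}

rnb <- function(n, mu, dispersion) {
  # NB with Var = mu + dispersion * mu^2; dispersion 0 degenerates to Poisson
  if (dispersion <= 0) return(stats::rpois(n, mu))
  stats::rnbinom(n, size = 1 / dispersion, mu = mu)
}

zero_pad <- function(i, width) formatC(i, width = width, flag = "0")

#' Simulate a nutrient-swap CRISPR knockout screen
#'
#' Emulates a pooled knockout screen read out by barcode sequencing:
#' per-sgRNA baseline abundances are lognormal, a pre-swap reference
#' sample is drawn per replicate, and final-timepoint counts in each
#' condition are negative-binomial around `baseline * 2^effect`, where
#' the planted effect is condition- and gene-specific. An expression
#' table is drawn so that planted genes are always expressed (they
#' survive the low-expression filter) while `frac_low_expressed` of the
#' remaining genes form a low-expression pool usable as an empirical
#' null.
#'
#' @param n_genes number of targeting genes (default 2000).
#' @param sgrnas_per_gene guides per gene (default 4).
#' @param n_noncutting non-cutting control guides, grouped 4 per
#'   control pseudo-gene (default 200).
#' @param replicates infection replicates (default 2).
#' @param conditions length-2 character; effects plant into the second
#'   (default `c("glucose", "uridine")`).
#' @param planted list with optional elements `specific` (genes
#'   essential only in `conditions[2]`), `shared` (essential in both);
#'   each either a gene count or a character vector of gene ids.
#' @param effect_log2 log2 depletion/enrichment of planted genes over
#'   the screen window (default -4, i.e. 16-fold depletion).
#' @param depth mean reads per sgRNA (default 500).
#' @param nb_dispersion negative-binomial dispersion (default 0.1).
#' @param frac_low_expressed fraction of unplanted genes drawn as
#'   low-expression (log2 FPKM < 0) null candidates (default 0.2).
#' @param seed master seed (default 0).
#' @return list with `counts` (a [count_matrix()] whose sample sheet
#'   has per-replicate `pre_swap_reference` samples and day-21 screen
#'   samples per condition), `library` (library map), `expression`
#'   (gene/log2_fpkm) and `truth` (per-gene planted effects).
#' @export
simulate_crispr_screen <- function(n_genes = 2000, sgrnas_per_gene = 4,
                                   n_noncutting = 200, replicates = 2,
                                   conditions = c("glucose", "uridine"),
                                   planted = list(specific = 100, shared = 0),
                                   effect_log2 = -4, depth = 500,
                                   nb_dispersion = 0.1,
                                   frac_low_expressed = 0.2, seed = 0) {
  stopifnot(length(conditions) == 2L, depth > 0, is.finite(effect_log2))
  genes <- paste0("GENE", zero_pad(seq_len(n_genes), 5L))
  ctrl_groups <- ceiling(n_noncutting / 4)
  ctrl_genes <- paste0("CTRL", zero_pad(seq_len(ctrl_groups), 3L))

  pick_set <- function(x, pool, stream) {
    if (is.character(x)) {
      bad <- setdiff(x, genes)
      if (length(bad))
        stop("planted gene(s) not in library: ",
             paste(utils::head(bad, 5L), collapse = ", "))
      return(x)
    }
    if (x == 0) return(character())
    with_stream(seed, stream, sample(pool, x))
  }
  spec <- pick_set(planted$specific %||% 0, genes, 1L)
  shared <- pick_set(planted$shared %||% 0, setdiff(genes, spec), 2L)

  lib <- data.frame(
    element_id = c(paste0(rep(genes, each = sgrnas_per_gene), "_sg",
                          seq_len(sgrnas_per_gene)),
                   paste0(rep(ctrl_genes, each = 4L), "_sg", 1:4)[seq_len(n_noncutting)]),
    gene = c(rep(genes, each = sgrnas_per_gene),
             rep(ctrl_genes, each = 4L)[seq_len(n_noncutting)]),
    class = rep(c("targeting", "control_noncutting"),
                c(n_genes * sgrnas_per_gene, n_noncutting)),
    stringsAsFactors = FALSE)
  n_el <- nrow(lib)

  effect <- matrix(0, n_el, 2L, dimnames = list(lib$element_id, conditions))
  effect[lib$gene %in% spec, 2L] <- effect_log2
  effect[lib$gene %in% shared, ] <- effect_log2

  abund <- with_stream(seed, 3L, stats::rlnorm(n_el, 0, 0.5))
  mu0 <- depth * abund / mean(abund)

  samples <- list(); meta <- list()
  for (r in seq_len(replicates)) {
    samples[[paste0("pre_rep", r)]] <-
      with_stream(seed, 10L + r, rnb(n_el, mu0, nb_dispersion))
    meta[[paste0("pre_rep", r)]] <-
      data.frame(condition = "pre_swap", replicate = r, day = 0,
                 role = "pre_swap_reference")
  }
  for (ci in 1:2) for (r in seq_len(replicates)) {
    id <- paste0(conditions[ci], "_rep", r)
    samples[[id]] <- with_stream(seed, 100L * ci + r,
                                 rnb(n_el, mu0 * 2^effect[, ci], nb_dispersion))
    meta[[id]] <- data.frame(condition = conditions[ci], replicate = r,
                             day = 21, role = "screen")
  }
  counts <- do.call(cbind, samples)
  rownames(counts) <- lib$element_id
  sample_meta <- do.call(rbind, meta)
  sample_meta <- data.frame(sample_id = names(samples), sample_meta,
                            stringsAsFactors = FALSE)

  n_low <- round(frac_low_expressed * n_genes)
  unplanted <- setdiff(genes, c(spec, shared))
  low <- with_stream(seed, 4L, sample(unplanted, min(n_low, length(unplanted))))
  log2_fpkm <- numeric(n_genes); names(log2_fpkm) <- genes
  log2_fpkm[] <- with_stream(seed, 5L, pmax(stats::rnorm(n_genes, 3, 2), 0))
  log2_fpkm[low] <- with_stream(seed, 6L,
                                pmin(stats::rnorm(length(low), -3, 1.5), -0.01))

  truth <- data.frame(gene = genes,
                      effect_a = ifelse(genes %in% shared, effect_log2, 0),
                      effect_b = ifelse(genes %in% c(spec, shared),
                                        effect_log2, 0),
                      planted_specific = genes %in% spec,
                      planted_shared = genes %in% shared,
                      stringsAsFactors = FALSE)
  names(truth)[2:3] <- paste0("effect_", conditions)

  list(counts = count_matrix(counts, sample_meta),
       library = lib,
       expression = data.frame(gene = genes, log2_fpkm = unname(log2_fpkm),
                               stringsAsFactors = FALSE),
       truth = truth,
       params = list(effect_log2 = effect_log2, depth = depth,
                     nb_dispersion = nb_dispersion, seed = seed))
}

#' Simulate a gain-of-function ORF proliferation screen
#'
#' One barcode per ORF; planted ORFs are enriched in the second
#' condition by `effect_log2`. Count noise is negative-binomial; at the
#' default depth 1000 and dispersion 0.01 the per-count coefficient of
#' variation is about 10%, a clean-screen regime.
#'
#' @param n_orfs number of ORF barcodes (default 2000).
#' @param replicates per condition (default 2).
#' @param conditions length-2 character (default
#'   `c("glucose", "galactose")`); enrichment plants into the second.
#' @param planted_enriched count or character vector of planted ORFs
#'   (default 20).
#' @param effect_log2 planted log2 enrichment (default 3).
#' @param depth mean reads per barcode (default 1000).
#' @param nb_dispersion NB dispersion (default 0.01).
#' @param day final timepoint in days (default 21).
#' @param seed master seed (default 0).
#' @return list with `counts` (day-0 and day-`day` samples), `truth`.
#' @export
simulate_orf_screen <- function(n_orfs = 2000, replicates = 2,
                                conditions = c("glucose", "galactose"),
                                planted_enriched = 20, effect_log2 = 3,
                                depth = 1000, nb_dispersion = 0.01,
                                day = 21, seed = 0) {
  stopifnot(length(conditions) == 2L, depth > 0, is.finite(effect_log2))
  orfs <- paste0("ORF", zero_pad(seq_len(n_orfs), 5L))
  planted <- if (is.character(planted_enriched)) {
    bad <- setdiff(planted_enriched, orfs)
    if (length(bad)) stop("planted ORF(s) not in library: ",
                          paste(utils::head(bad, 5L), collapse = ", "))
    planted_enriched
  } else if (planted_enriched > 0) {
    with_stream(seed, 1L, sample(orfs, planted_enriched))
  } else character()

  abund <- with_stream(seed, 2L, stats::rlnorm(n_orfs, 0, 0.5))
  mu0 <- depth * abund / mean(abund)
  eff <- ifelse(orfs %in% planted, effect_log2, 0)

  samples <- list(); meta <- list()
  for (r in seq_len(replicates)) {
    id <- paste0("day0_rep", r)
    samples[[id]] <- with_stream(seed, 10L + r, rnb(n_orfs, mu0, nb_dispersion))
    meta[[id]] <- data.frame(condition = "baseline", replicate = r, day = 0,
                             role = "day0")
  }
  for (ci in 1:2) for (r in seq_len(replicates)) {
    id <- paste0(conditions[ci], "_rep", r)
    mu <- if (ci == 2L) mu0 * 2^eff else mu0
    samples[[id]] <- with_stream(seed, 100L * ci + r,
                                 rnb(n_orfs, mu, nb_dispersion))
    meta[[id]] <- data.frame(condition = conditions[ci], replicate = r,
                             day = day, role = "screen")
  }
  counts <- do.call(cbind, samples)
  rownames(counts) <- orfs
  sample_meta <- data.frame(sample_id = names(samples),
                            do.call(rbind, meta), stringsAsFactors = FALSE)
  list(counts = count_matrix(counts, sample_meta),
       truth = data.frame(element_id = orfs,
                          effect_log2 = eff,
                          planted = orfs %in% planted,
                          stringsAsFactors = FALSE),
       params = list(effect_log2 = effect_log2, depth = depth,
                     nb_dispersion = nb_dispersion, seed = seed))
}

#' Simulate a multiplexed barcoded cell-line competition assay
#'
#' Emulates a pooled growth screen across cancer cell lines from
#' `n_lineages` lineages: each line has a latent differential-growth
#' value (log2 uridine vs glucose), one lineage carries a planted
#' shift, and one molecular feature is generated with true correlation
#' `r_true` to the latent values among `n_features` otherwise
#' independent features. Barcode counts are negative-binomial around
#' the growth-implied means, so the closed-form growth metrics recover
#' the latent values within counting noise.
#'
#' @param n_lines cell lines (default 482).
#' @param n_lineages lineages (default 22); the planted lineage has
#'   `planted_members` lines (default 20), the rest are split evenly.
#' @param replicates replicate wells per condition (default 3).
#' @param lineage_shift planted mean lfc shift of the first lineage in
#'   log2 units (default 2); 0 plants nothing.
#' @param planted_members lines in the planted lineage (default 20).
#' @param n_features molecular features (default 2000); 0 disables the
#'   feature matrix.
#' @param r_true correlation of the planted feature with the latent
#'   lfc (default 0.6); 0 plants no correlated feature.
#' @param baseline_sd sd of the latent per-line lfc (default 0.5).
#' @param n0 seeding-scale count per line (default 200).
#' @param growth_mean,growth_sd glucose-arm growth rate distribution
#'   in doublings/day (defaults 0.7, 0.15).
#' @param t_days assay length in days (default 6).
#' @param nb_dispersion count dispersion (default 0.04, ~20% CV).
#' @param seed master seed (default 0).
#' @return list with `records` (replicate-level count table for
#'   [prism_metrics()]), `features` (matrix or NULL), `truth`.
#' @export
simulate_prism <- function(n_lines = 482, n_lineages = 22, replicates = 3,
                           lineage_shift = 2, planted_members = 20,
                           n_features = 2000, r_true = 0.6,
                           baseline_sd = 0.5, n0 = 200,
                           growth_mean = 0.7, growth_sd = 0.15,
                           t_days = 6, nb_dispersion = 0.04, seed = 0) {
  stopifnot(n_lineages <= n_lines, planted_members < n_lines,
            abs(r_true) <= 1)
  lines <- paste0("LINE", zero_pad(seq_len(n_lines), 4L))
  lineages <- paste0("lineage_", zero_pad(seq_len(n_lineages), 2L))
  lin <- character(n_lines)
  lin[seq_len(planted_members)] <- lineages[1L]
  rest <- seq(planted_members + 1L, n_lines)
  lin[rest] <- rep(lineages[-1L], length.out = length(rest))

  lfc_latent <- with_stream(seed, 1L, stats::rnorm(n_lines, 0, baseline_sd))
  planted_lineage <- if (lineage_shift != 0) lineages[1L] else NA_character_
  if (lineage_shift != 0)
    lfc_latent[lin == lineages[1L]] <- lfc_latent[lin == lineages[1L]] +
      lineage_shift

  g_rate <- with_stream(seed, 2L, stats::rnorm(n_lines, growth_mean, growth_sd))
  mu_g <- n0 * 2^(g_rate * t_days)
  mu_u <- mu_g * 2^lfc_latent

  rec <- do.call(rbind, lapply(seq_len(replicates), function(r) {
    data.frame(cell_line = lines, lineage = lin, replicate = r,
               n_g = with_stream(seed, 10L + r,
                                 rnb(n_lines, mu_g, nb_dispersion)),
               n_u = with_stream(seed, 20L + r,
                                 rnb(n_lines, mu_u, nb_dispersion)),
               n_0 = rep(n0, n_lines),
               stringsAsFactors = FALSE)
  }))

  features <- NULL; planted_feature <- NA_character_
  if (n_features > 0) {
    features <- with_stream(seed, 3L,
                            matrix(stats::rnorm(n_lines * n_features),
                                   n_lines, n_features))
    dimnames(features) <- list(lines,
                               paste0("FEAT", zero_pad(seq_len(n_features), 4L)))
    if (r_true != 0) {
      planted_feature <- "FEAT0001"
      z <- as.numeric(scale(lfc_latent))
      eps <- with_stream(seed, 4L, stats::rnorm(n_lines))
      features[, planted_feature] <- r_true * z + sqrt(1 - r_true^2) * eps
    }
  }
  list(records = rec, features = features,
       truth = list(lfc_latent = stats::setNames(lfc_latent, lines),
                    lineage = stats::setNames(lin, lines),
                    planted_lineage = planted_lineage,
                    planted_feature = planted_feature,
                    r_true = r_true, lineage_shift = lineage_shift),
       params = list(replicates = replicates, t_days = t_days, n0 = n0,
                     nb_dispersion = nb_dispersion, seed = seed))
}

#' Simulate measured isotopologue intensities
#'
#' Convolves a true MID with the natural-abundance matrix, scales to an
#' arbitrary total intensity, and applies multiplicative lognormal
#' measurement noise with coefficient of variation `noise_cv`.
#'
#' @param n_carbons carbon count.
#' @param true_mid true tracer-derived MID (length `n_carbons + 1`,
#'   sums to 1).
#' @param p natural 13C abundance (default 0.0107).
#' @param noise_cv multiplicative noise CV (default 0.02); 0 gives a
#'   noiseless convolution.
#' @param intensity total measured intensity scale (default 1e6).
#' @param n_samples replicate measurements (default 1).
#' @param metabolite metabolite name for the output table.
#' @param seed master seed (default 0).
#' @return list with `mids` (data frame in [correct_mid_table()]
#'   layout, one row per replicate) and `truth` (the true MID).
#' @export
simulate_mids <- function(n_carbons, true_mid, p = 0.0107, noise_cv = 0.02,
                          intensity = 1e6, n_samples = 1,
                          metabolite = "metabolite", seed = 0) {
  true_mid <- as.numeric(true_mid)
  if (length(true_mid) != n_carbons + 1L)
    stop("true_mid must have length n_carbons + 1")
  if (abs(sum(true_mid) - 1) > 1e-8) stop("true_mid must sum to 1")
  if (any(true_mid < 0)) stop("true_mid fractions must be nonnegative")
  C <- natural_abundance_matrix(n_carbons, p)
  expected <- as.numeric(C %*% true_mid) * intensity
  sdlog <- sqrt(log(1 + noise_cv^2))
  rows <- lapply(seq_len(n_samples), function(i) {
    noise <- if (noise_cv > 0)
      with_stream(seed, i, stats::rlnorm(n_carbons + 1L, -sdlog^2 / 2, sdlog))
    else rep(1, n_carbons + 1L)
    raw <- expected * noise
    stats::setNames(as.list(raw), paste0("M", 0:n_carbons))
  })
  mids <- data.frame(metabolite = paste0(metabolite,
                                         if (n_samples > 1) paste0("_rep", seq_len(n_samples)) else ""),
                     n_carbons = n_carbons,
                     do.call(rbind, lapply(rows, as.data.frame)),
                     stringsAsFactors = FALSE)
  rownames(mids) <- NULL
  list(mids = mids, truth = list(true_mid = true_mid, p = p,
                                 noise_cv = noise_cv, seed = seed))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
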