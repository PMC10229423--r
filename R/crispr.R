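#' Gene-level mean log2 fold change from sgRNA-level values
#'
#' For one screen sample against a pre-swap reference, computes each
#' element's log2 fold change and averages elements within a gene
#' (typically the 4 sgRNAs of a knockout library). Non-cutting control
#' elements aggregate under their own pseudo-gene labels exactly like
#' targeting genes; their class is reported so downstream steps can
#' tell them apart.
#'
#' @param norm a `norm_matrix` from [normalize_log2_rpm()].
#' @param lib library map data frame ([read_library_map()]).
#' @param reference sample id of the pre-swap reference (its role in
#'   the sample sheet must be `pre_swap_reference`).
#' @param sample sample id of the screen sample.
#' @return data frame with columns `gene`, `lfc` (mean over elements),
#'   `n_elements`, `class`.
#' @export
gene_level_lfc <- function(norm, lib, reference, sample) {
  stopifnot(inherits(norm, "norm_matrix"))
  lib <- read_library_map(lib)
  meta <- norm$sample_meta
  role <- meta$role[meta$sample_id == reference]
  if (!length(role) || role != "pre_swap_reference")
    stop("reference sample '", reference,
         "' must have role 'pre_swap_reference'")
  lfc <- log2_fold_change(norm, sample, reference)
  idx <- match(names(lfc), lib$element_id)
  if (anyNA(idx))
    stop("element(s) missing from library map: ",
         paste(utils::head(names(lfc)[is.na(idx)], 5L), collapse = ", "))
  gene <- lib$gene[idx]
  agg <- vapply(split(lfc, gene), mean, 0)
  n_el <- vapply(split(lfc, gene), length, 0L)
  cls <- vapply(split(lib$class[idx], gene), function(x) x[1L], "")
  empty <- setdiff(unique(lib$gene), names(agg))
  if (length(empty))
    warning("gene(s) with zero mapped elements excluded: ",
            paste(utils::head(empty, 5L), collapse = ", "))
  out <- data.frame(gene = names(agg), lfc = unname(agg),
                    n_elements = unname(n_el), class = unname(cls),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$gene), ]
}

#' Filter genes to the expressed set
#'
#' Removes genes whose expression is strictly below `threshold` log2
#' FPKM; a gene exactly at the threshold is retained. Genes absent
#' from the expression table cannot be ranked and are removed.
#'
#' @param genes character vector of gene ids.
#' @param expr expression table ([read_expression_table()]).
#' @param threshold log2 FPKM cutoff (default 0).
#' @return character vector of retained genes (original order).
#' @export
filter_expressed <- function(genes, expr, threshold = 0) {
  expr <- read_expression_table(expr)
  e <- expr$log2_fpkm[match(genes, expr$gene)]
  genes[!is.na(e) & e >= threshold]
}

#' Build an empirical null model for essentiality z-scoring
#'
#' The null is defined by the `k` genes with the lowest expression:
#' sgRNAs against genes a cell does not express should have no fitness
#' effect, so the spread of their gene-level LFCs estimates the
#' technical noise floor. Ties at the k-th expression rank are broken
#' lexicographically by gene id.
#'
#' @param mean_lfcs named numeric vector of per-gene mean LFCs (or a
#'   data frame with `gene` and `lfc` columns).
#' @param expr expression table; only genes present both here and in
#'   `mean_lfcs` are eligible. `-Inf` (zero FPKM) is a valid value and
#'   ranks lowest.
#' @param k number of null member genes (>= 2). Genome-scale analyses
#'   following the reference workflow use k = 3726.
#' @return object of class `null_model`: list with `member_genes`,
#'   `mu`, `sigma` (sample sd), `k`, `mode = "expression"`.
#' @export
build_null <- function(mean_lfcs, expr, k) {
  mean_lfcs <- as_gene_vector(mean_lfcs)
  expr <- read_expression_table(expr)
  common <- intersect(expr$gene, names(mean_lfcs))
  if (k < 2L) stop("null model needs k >= 2")
  if (k > length(common))
    stop("k = ", k, " exceeds the ", length(common),
         " genes with both expression and LFC values")
  e <- expr$log2_fpkm[match(common, expr$gene)]
  ord <- order(e, common)           # ties broken lexicographically
  members <- common[ord][seq_len(k)]
  new_null_model(mean_lfcs[members], members, "expression")
}

#' Build a null model from non-cutting control pseudo-genes
#'
#' Alternative calibration: the null members are the non-cutting
#' control pseudo-genes (library elements with no genomic target),
#' whose LFC spread likewise estimates effect-free noise.
#'
#' @param gene_lfcs data frame from [gene_level_lfc()] (needs the
#'   `class` column to identify controls).
#' @return a `null_model` with `mode = "noncutting"`.
#' @export
build_null_noncutting <- function(gene_lfcs) {
  stopifnot(is.data.frame(gene_lfcs), "class" %in% names(gene_lfcs))
  ctrl <- gene_lfcs[gene_lfcs$class == "control_noncutting", ]
  if (nrow(ctrl) < 2L)
    stop("need >= 2 non-cutting control pseudo-genes, got ", nrow(ctrl))
  v <- stats::setNames(ctrl$lfc, ctrl$gene)
  new_null_model(v, ctrl$gene, "noncutting")
}

new_null_model <- function(values, members, mode) {
  mu <- mean(values)
  sigma <- stats::sd(values)        # sample sd, ddof 1
  if (!is.finite(sigma) || sigma == 0)
    stop("degenerate null: member LFCs have zero spread")
  structure(list(member_genes = members, mu = mu, sigma = sigma,
                 k = length(members), mode = mode),
            class = "null_model")
}

#' @export
print.null_model <- function(x, ...) {
  cat(sprintf("null_model (%s): k = %d, mu = %.4g, sigma = %.4g\n",
              x$mode, x$k, x$mu, x$sigma))
  invisible(x)
}

#' z-score gene LFCs against a null model
#'
#' @param mean_lfcs named numeric vector (or `gene`/`lfc` data frame).
#' @param null a `null_model`.
#' @return named numeric vector of z-scores, `(lfc - mu) / sigma`.
#' @export
zscore_genes <- function(mean_lfcs, null) {
  stopifnot(inherits(null, "null_model"))
  v <- as_gene_vector(mean_lfcs)
  (v - null$mu) / null$sigma
}

as_gene_vector <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("gene", "lfc") %in% names(x)))
    return(stats::setNames(x$lfc, x$gene))
  }
  if (is.null(names(x))) stop("gene LFCs must be named by gene")
  x
}

#' Score one condition of a CRISPR knockout screen
#'
#' Full per-condition pipeline: normalize, compute per-replicate
#' gene-level LFCs against the matching pre-swap reference, average
#' across replicates, filter to expressed genes, and z-score against an
#' empirical null. References are matched to screen replicates by
#' replicate number when several pre-swap samples exist; a single
#' pre-swap sample serves all replicates.
#'
#' @param m a [count_matrix()].
#' @param lib library map.
#' @param expr expression table (log2 FPKM).
#' @param condition condition label of the screen samples to score.
#' @param null_mode `"expression"` (null from the `null_k`
#'   lowest-expressed genes; the procedural default) or `"noncutting"`
#'   (null from non-cutting control pseudo-genes).
#' @param null_k null size for `"expression"` mode; `NULL` picks 20% of
#'   the scoreable genes (genome-scale workflows use 3726).
#' @param expr_threshold log2 FPKM cutoff for the expressed-set filter.
#' @return list (class `crispr_scores`) with `scores` (data frame:
#'   `gene`, `lfc`, `z`, `n_elements`), `null` (the `null_model`),
#'   `condition`, and `gene_lfcs` (pre-filter table incl. controls).
#' @export
score_crispr_condition <- function(m, lib, expr, condition,
                                   null_mode = c("expression", "noncutting"),
                                   null_k = NULL, expr_threshold = 0) {
  null_mode <- match.arg(null_mode)
  stopifnot(inherits(m, "count_matrix"))
  lib <- read_library_map(lib)
  check_library_counts(lib, m)
  expr <- read_expression_table(expr)
  meta <- m$sample_meta
  screens <- meta[meta$condition == condition & meta$role == "screen", ]
  if (!nrow(screens)) stop("no screen samples for condition '", condition, "'")
  refs <- meta[meta$role == "pre_swap_reference", ]
  if (!nrow(refs)) stop("no pre_swap_reference sample in the sample sheet")
  norm <- normalize_log2_rpm(m)

  per_rep <- lapply(seq_len(nrow(screens)), function(i) {
    rep_i <- screens$replicate[i]
    ref <- if (nrow(refs) == 1L) refs$sample_id else {
      cand <- refs$sample_id[refs$replicate == rep_i]
      if (!length(cand))
        stop("no pre_swap_reference for replicate ", rep_i)
      cand[1L]
    }
    gene_level_lfc(norm, lib, ref, screens$sample_id[i])
  })
  # genes are identical and sorted across replicates by construction
  base <- per_rep[[1L]]
  lfc_mat <- vapply(per_rep, `[[`, numeric(nrow(base)), "lfc")
  gene_lfcs <- data.frame(gene = base$gene,
                          lfc = rowMeans(as.matrix(lfc_mat)),
                          n_elements = base$n_elements,
                          class = base$class,
                          stringsAsFactors = FALSE)

  targeting <- gene_lfcs[gene_lfcs$class == "targeting", ]
  mean_lfcs <- stats::setNames(targeting$lfc, targeting$gene)
  null <- switch(null_mode,
    expression = {
      k <- if (is.null(null_k))
        max(2L, floor(0.2 * sum(targeting$gene %in% expr$gene)))
      else as.integer(null_k)
      build_null(mean_lfcs, expr, k)
    },
    noncutting = build_null_noncutting(gene_lfcs))

  keep <- filter_expressed(targeting$gene, expr, expr_threshold)
  scored <- targeting[targeting$gene %in% keep, c("gene", "lfc", "n_elements")]
  scored$z <- unname(zscore_genes(
    stats::setNames(scored$lfc, scored$gene), null))
  scored <- scored[, c("gene", "lfc", "z", "n_elements")]
  rownames(scored) <- NULL
  structure(list(scores = scored, null = null, condition = condition,
                 gene_lfcs = gene_lfcs),
            class = "crispr_scores")
}

#' Differential essentiality between two conditions
#'
#' Joins per-gene z-scores from two conditions (inner join on gene,
#' with a message when the sets differ) and classifies each gene by
#' configurable thresholds. The default convention calls a gene
#' essential in a condition at `z <= z_essential` and
#' condition-specific when the other condition's z exceeds `z_spared`;
#' these cutoffs are reporting conventions of this package, not
#' estimated quantities.
#'
#' @param z_a,z_b named z-score vectors (e.g. glucose and uridine).
#'   `dz = z_b - z_a`, so negative `dz` means more essential in `b`.
#' @param z_essential essentiality cutoff (default -3).
#' @param z_spared dispensability cutoff for the other condition
#'   (default -1).
#' @param labels length-2 character: condition names used in the
#'   `class` column (default `c("a", "b")`).
#' @return data frame with `gene`, `z_a`, `z_b`, `dz`, `class` where
#'   class is one of `<b>_specific_essential`, `<a>_specific_essential`,
#'   `shared_essential`, `neutral`; sorted by ascending `dz`.
#' @export
differential_essentiality <- function(z_a, z_b, z_essential = -3,
                                      z_spared = -1,
                                      labels = c("a", "b")) {
  stopifnot(length(labels) == 2L)
  common <- intersect(names(z_a), names(z_b))
  if (length(common) < length(z_a) || length(common) < length(z_b))
    message("gene sets differ; inner join keeps ", length(common), " genes")
  za <- z_a[common]; zb <- z_b[common]
  cls <- rep("neutral", length(common))
  ess_a <- za <= z_essential; ess_b <- zb <= z_essential
  cls[ess_a & ess_b] <- "shared_essential"
  cls[ess_b & !ess_a & za > z_spared] <-
    paste0(labels[2L], "_specific_essential")
  cls[ess_a & !ess_b & zb > z_spared] <-
    paste0(labels[1L], "_specific_essential")
  out <- data.frame(gene = common, z_a = unname(za), z_b = unname(zb),
                    dz = unname(zb - za), class = cls,
                    stringsAsFactors = FALSE)
  names(out)[2:3] <- paste0("z_", labels)
  out <- out[order(out$dz, out$gene), ]
  rownames(out) <- NULL
  out
}
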