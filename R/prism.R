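#' Validate a table of multiplexed barcoded growth-assay records
#'
#' One row per cell line and replicate with barcode counts from the
#' two competing conditions plus the initial-timepoint count:
#' columns `cell_line`, `lineage`, `replicate`, `n_g` (glucose-arm
#' count), `n_u` (uridine-arm count), `n_0` (initial count, constant
#' within a cell line).
#'
#' @param records data frame (or TSV path) with the columns above.
#' @return validated data frame.
#' @export
read_prism_records <- function(records) {
  rec <- if (is.data.frame(records)) records else read_tsv_commented(records)
  req <- c("cell_line", "lineage", "replicate", "n_g", "n_u", "n_0")
  miss <- setdiff(req, names(rec))
  if (length(miss))
    stop("growth-assay records missing column(s): ",
         paste(miss, collapse = ", "))
  rec <- as.data.frame(rec)[, req]
  rec$cell_line <- as.character(rec$cell_line)
  rec$lineage <- as.character(rec$lineage)
  for (col in c("n_g", "n_u", "n_0")) {
    v <- rec[[col]]
    if (any(!is.na(v) & v < 0)) stop("negative counts in column ", col)
  }
  rec
}

#' Mask unexpectedly low replicate counts
#'
#' Replicate-level counts below `floor` (for example sequencing noise)
#' are set to missing so they do not depress the collapsed mean.
#' Applies to the condition counts `n_g` and `n_u`; the initial count
#' `n_0` is left untouched.
#'
#' @param records record table ([read_prism_records()]).
#' @param floor minimum credible raw count (default 20); `floor = 0`
#'   leaves the table unchanged.
#' @return the table with sub-floor values replaced by `NA`.
#' @export
filter_low_counts <- function(records, floor = 20) {
  stopifnot(floor >= 0)
  rec <- read_prism_records(records)
  for (col in c("n_g", "n_u"))
    rec[[col]][!is.na(rec[[col]]) & rec[[col]] < floor] <- NA_real_
  rec
}

#' Mean-collapse replicates to per-line condition counts
#'
#' Arithmetic mean of the unmasked raw counts per cell line and
#' condition; masked (`NA`) replicates are excluded from the
#' denominator. Lines whose replicates are all masked in a condition
#' get a missing collapsed count (and a message).
#'
#' @param records record table, typically after [filter_low_counts()].
#' @return data frame with one row per cell line: `cell_line`,
#'   `lineage`, `n_g`, `n_u`, `n_0`.
#' @export
collapse_replicates <- function(records) {
  rec <- read_prism_records(records)
  mean_ok <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  sp <- split(rec, rec$cell_line)
  out <- do.call(rbind, lapply(sp, function(d) {
    data.frame(cell_line = d$cell_line[1L], lineage = d$lineage[1L],
               n_g = mean_ok(d$n_g), n_u = mean_ok(d$n_u),
               n_0 = mean_ok(d$n_0), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  dropped <- out$cell_line[is.na(out$n_g) | is.na(out$n_u)]
  if (length(dropped))
    message(length(dropped),
            " cell line(s) with all replicates masked in a condition: ",
            paste(utils::head(dropped, 5L), collapse = ", "))
  out[order(out$cell_line), ]
}

#' Log2 fold change between the two assay arms
#'
#' `log2(n_u / n_g)` on collapsed counts. Nonpositive or missing
#' counts yield a missing value, never +/-Inf.
#'
#' @param n_u,n_g collapsed counts from the uridine and glucose arms.
#' @return numeric vector.
#' @export
prism_lfc <- function(n_u, n_g) {
  out <- rep(NA_real_, length(n_u))
  ok <- !is.na(n_u) & !is.na(n_g) & n_u > 0 & n_g > 0
  out[ok] <- log2(n_u[ok] / n_g[ok])
  out
}

#' Growth rate in doublings per day
#'
#' `log2(n_f / n_0) / t` for an assay of length `t` days.
#'
#' @param n_0,n_f initial- and final-timepoint counts.
#' @param t assay length in days (> 0); the screen design here runs
#'   6 days.
#' @return numeric vector (doublings/day); missing where counts are
#'   nonpositive or missing.
#' @export
growth_rate <- function(n_0, n_f, t = 6) {
  if (any(t <= 0)) stop("assay length t must be positive")
  out <- rep(NA_real_, length(n_f))
  ok <- !is.na(n_0) & !is.na(n_f) & n_0 > 0 & n_f > 0
  out[ok] <- log2(n_f[ok] / n_0[ok]) / t
  out
}

#' Per-line growth metrics for a multiplexed competition assay
#'
#' Pipeline: mask low counts, mean-collapse replicates, then compute
#' the uridine-vs-glucose log2 fold change and per-arm growth rates on
#' the collapsed counts (collapse first, then ratio).
#'
#' @param records record table ([read_prism_records()]).
#' @param floor low-count mask threshold (default 20 raw counts).
#' @param t_days assay length in days (default 6).
#' @return data frame with `cell_line`, `lineage`, `lfc`,
#'   `growth_rate_glu`, `growth_rate_uri`.
#' @export
prism_metrics <- function(records, floor = 20, t_days = 6) {
  col <- collapse_replicates(filter_low_counts(records, floor))
  data.frame(cell_line = col$cell_line, lineage = col$lineage,
             lfc = prism_lfc(col$n_u, col$n_g),
             growth_rate_glu = growth_rate(col$n_0, col$n_g, t_days),
             growth_rate_uri = growth_rate(col$n_0, col$n_u, t_days),
             stringsAsFactors = FALSE)
}

#' Lineage enrichment of differential growth
#'
#' For each lineage, the effect is the mean member `lfc` minus the mean
#' of all other lines, with a two-sided pooled Student's t-test
#' (members vs rest) and Benjamini-Hochberg adjustment across the
#' tested lineages. Lineages with fewer than `min_members` non-missing
#' members are flagged and not tested.
#'
#' @param metrics output of [prism_metrics()] (needs `lfc`, `lineage`).
#' @param min_members minimum member lines with a metric (default 3).
#' @return data frame with `lineage`, `n`, `effect`, `p`, `q`,
#'   `tested`, sorted by `p`.
#' @export
lineage_enrichment <- function(metrics, min_members = 3) {
  stopifnot(all(c("lineage", "lfc") %in% names(metrics)))
  ok <- !is.na(metrics$lfc)
  lfc <- metrics$lfc[ok]; lin <- metrics$lineage[ok]
  lineages <- sort(unique(metrics$lineage))
  if (length(lineages) < 2L) stop("need >= 2 lineages")
  rows <- lapply(lineages, function(L) {
    inL <- lin == L
    n <- sum(inL)
    if (n < min_members || sum(!inL) < 2L)
      return(data.frame(lineage = L, n = n, effect = NA_real_,
                        p = NA_real_, tested = FALSE))
    tt <- t_test_two_sided(lfc[inL], lfc[!inL])
    data.frame(lineage = L, n = n,
               effect = mean(lfc[inL]) - mean(lfc[!inL]),
               p = tt$p, tested = TRUE)
  })
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  out$q[out$tested] <- benjamini_hochberg(out$p[out$tested])
  out <- out[order(out$p, out$lineage), c("lineage", "n", "effect",
                                          "p", "q", "tested")]
  rownames(out) <- NULL
  out
}

#' Correlate differential growth with molecular features
#'
#' Pearson correlation (Spearman via `method`) between each feature and
#' the per-line `lfc`, with pairwise-complete handling of missing
#' values; p-values come from the t-distribution transform of r and are
#' BH-adjusted within each feature class. Features observed on fewer
#' than `min_lines` lines, or constant across them, are excluded with a
#' warning.
#'
#' @param metrics output of [prism_metrics()].
#' @param features numeric matrix, cell lines in rows (rownames =
#'   cell_line), features in columns.
#' @param feature_class single label or per-column character vector
#'   (`transcript`, `protein`, `copy_number`, ...); BH adjustment is
#'   within class.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param min_lines minimum overlapping lines per feature (default 3).
#' @return data frame with `feature`, `feature_class`, `n`, `r`, `p`,
#'   `q`, sorted by decreasing `|r|`.
#' @export
biomarker_correlation <- function(metrics, features,
                                  feature_class = "feature",
                                  method = c("pearson", "spearman"),
                                  min_lines = 3) {
  method <- match.arg(method)
  stopifnot(is.matrix(features), !is.null(rownames(features)),
            !is.null(colnames(features)))
  if (length(feature_class) == 1L)
    feature_class <- rep(feature_class, ncol(features))
  stopifnot(length(feature_class) == ncol(features))
  common <- intersect(metrics$cell_line, rownames(features))
  if (length(common) < min_lines)
    stop("fewer than ", min_lines, " cell lines shared between metrics and features")
  lfc <- metrics$lfc[match(common, metrics$cell_line)]
  X <- features[common, , drop = FALSE]
  if (method == "spearman") {
    lfc <- rank(lfc, na.last = "keep")
    X <- apply(X, 2L, rank, na.last = "keep")
  }
  pair_ok <- !is.na(X) & !is.na(lfc)
  n <- colSums(pair_ok)
  r <- suppressWarnings(stats::cor(X, lfc, use = "pairwise.complete.obs"))[, 1L]
  sd0 <- is.na(r) & n >= min_lines    # constant feature over the overlap
  drop <- n < min_lines | sd0
  if (any(sd0))
    warning(sum(sd0), " constant feature(s) excluded (correlation undefined)")
  out <- data.frame(feature = colnames(X), feature_class = feature_class,
                    n = n, r = unname(r), stringsAsFactors = FALSE)
  out <- out[!drop, ]
  out$p <- pearson_p(out$r, out$n)
  out$q <- NA_real_
  for (cl in unique(out$feature_class)) {
    sel <- out$feature_class == cl
    out$q[sel] <- benjamini_hochberg(out$p[sel])
  }
  out <- out[order(-abs(out$r), out$feature), ]
  rownames(out) <- NULL
  out
}
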