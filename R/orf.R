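#' Score a gain-of-function ORF proliferation screen
#'
#' Contrasts barcode abundance between two growth conditions at a
#' single day. Counts are log2-RPM normalized ([normalize_log2_rpm()]),
#' then per element the log2 fold change is the mean normalized value
#' in `condition_b` minus the mean in `condition_a`, and a pooled
#' two-sided Student's t-test compares the per-replicate normalized
#' values of the two conditions (see [t_test_two_sided()]; p-values are
#' not adjusted for multiple comparisons). Positive `lfc` means
#' enrichment in `condition_b`.
#'
#' Strong depleters can reflect lentiviral recombination artifacts
#' rather than biology, so rows below `deplete_flag` log2 units are
#' flagged (`flag_depleted`), never filtered.
#'
#' @param m a [count_matrix()] containing `role == "screen"` samples
#'   for both conditions at `day`, with >= 2 replicates each.
#' @param condition_a,condition_b condition labels; `lfc > 0` means
#'   higher abundance in `condition_b`.
#' @param day the timepoint (days) at which to contrast conditions.
#' @param lib optional library map (data frame from
#'   [read_library_map()]); if supplied, a `gene` column is added and,
#'   when several elements share a gene, gene-level mean LFCs are also
#'   returned as an attribute `gene_level`.
#' @param deplete_flag flag threshold in log2 units (default -3).
#' @return data frame (class `orf_scores`) with columns `element_id`,
#'   `gene` (if `lib` given), `lfc`, `t`, `p`, `flag_depleted`, sorted
#'   by descending `lfc`.
#' @export
score_orf_screen <- function(m, condition_a, condition_b, day,
                             lib = NULL, deplete_flag = -3) {
  stopifnot(inherits(m, "count_matrix"))
  meta <- m$sample_meta
  pick <- function(cond) meta$sample_id[meta$condition == cond &
                                          meta$day == day &
                                          meta$role == "screen"]
  sa <- pick(condition_a); sb <- pick(condition_b)
  if (length(sa) < 2L || length(sb) < 2L)
    stop(sprintf("need >= 2 replicate screen samples per condition at day %s (got %d for '%s', %d for '%s')",
                 format(day), length(sa), condition_a, length(sb), condition_b))
  norm <- normalize_log2_rpm(m)
  xa <- norm$values[, sa, drop = FALSE]
  xb <- norm$values[, sb, drop = FALSE]
  tt <- row_t_test(xb, xa)
  if (any(tt$degenerate))
    message(sum(tt$degenerate),
            " element(s) with zero pooled variance; degenerate t convention applied")
  res <- data.frame(element_id = rownames(norm$values),
                    lfc = rowMeans(xb) - rowMeans(xa),
                    t = tt$t, p = tt$p,
                    stringsAsFactors = FALSE)
  res$flag_depleted <- res$lfc <= deplete_flag
  if (!is.null(lib)) {
    lib <- read_library_map(lib)
    check_library_counts(lib, m)
    res$gene <- lib$gene[match(res$element_id, lib$element_id)]
    res <- res[, c("element_id", "gene", "lfc", "t", "p", "flag_depleted")]
  }
  res <- res[order(-res$lfc, res$element_id), ]
  rownames(res) <- NULL
  if (!is.null(lib) && anyDuplicated(res$gene)) {
    gl <- aggregate(lfc ~ gene, data = res, FUN = mean)
    attr(res, "gene_level") <- gl[order(-gl$lfc, gl$gene), ]
  }
  class(res) <- c("orf_scores", "data.frame")
  res
}

#' Render ORF scores as a volcano-plot table
#'
#' Adds a `neg_log10_p` column (capped so that the degenerate `p = 0`
#' convention renders finitely) and writes a deterministic TSV.
#'
#' @param scores output of [score_orf_screen()].
#' @param path optional output path; if `NULL` the table is returned
#'   without writing.
#' @param cap cap for `-log10(p)` (default 300).
#' @param params named list echoed into the file comment header.
#' @return the volcano table, invisibly if written.
#' @export
volcano_table <- function(scores, path = NULL, cap = 300, params = list()) {
  stopifnot(is.data.frame(scores), nrow(scores) > 0L)
  tab <- as.data.frame(scores)
  tab$neg_log10_p <- pmin(-log10(tab$p), cap)
  keep <- intersect(c("element_id", "gene", "lfc", "p", "neg_log10_p"),
                    names(tab))
  tab <- tab[, keep]
  if (is.null(path)) return(tab)
  write_tsv_commented(tab, path, params)
  invisible(tab)
}
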