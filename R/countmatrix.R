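SAMPLE_ROLES <- c("screen", "pre_swap_reference", "day0")
ELEMENT_CLASSES <- c("targeting", "control_noncutting")

#' Construct a validated element-by-sample count matrix
#'
#' A `count_matrix` couples a nonnegative integer matrix of sequencing
#' counts (rows: library elements such as sgRNAs, ORF barcodes or
#' cell-line barcodes; columns: samples) with a per-sample metadata
#' table describing condition, replicate, day and role.
#'
#' @param counts integer matrix with unique rownames (element ids) and
#'   colnames (sample ids); all entries must be nonnegative integers.
#' @param sample_meta data frame with columns `sample_id`, `condition`,
#'   `replicate` (positive integer), `day` (nonnegative number) and
#'   `role` (one of `"screen"`, `"pre_swap_reference"`, `"day0"`), one
#'   row per column of `counts`.
#' @return an object of class `count_matrix`: a list with elements
#'   `counts` and `sample_meta`.
#' @export
count_matrix <- function(counts, sample_meta) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have element ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate element id: ",
         rownames(counts)[duplicated(rownames(counts))][1L])
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample id: ",
         colnames(counts)[duplicated(colnames(counts))][1L])
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("counts must be nonnegative integers; offending cell at row '%s', column '%s' (value %s)",
                 rownames(counts)[bad[1L, 1L]], colnames(counts)[bad[1L, 2L]],
                 format(counts[bad[1L, , drop = FALSE]])))
  }
  storage.mode(counts) <- "double"  # counts can exceed .Machine$integer.max in pooled screens
  sample_meta <- validate_sample_meta(sample_meta, colnames(counts))
  structure(list(counts = counts, sample_meta = sample_meta),
            class = "count_matrix")
}

validate_sample_meta <- function(sample_meta, sample_ids) {
  req <- c("sample_id", "condition", "replicate", "day", "role")
  miss <- setdiff(req, names(sample_meta))
  if (length(miss))
    stop("sample sheet is missing column(s): ", paste(miss, collapse = ", "))
  sample_meta <- as.data.frame(sample_meta)[, req]
  sample_meta$sample_id <- as.character(sample_meta$sample_id)
  if (anyDuplicated(sample_meta$sample_id))
    stop("duplicate sample_id in sample sheet")
  if (!setequal(sample_meta$sample_id, sample_ids))
    stop("sample sheet ids do not match count matrix columns; missing: ",
         paste(setdiff(sample_ids, sample_meta$sample_id), collapse = ", "))
  sample_meta <- sample_meta[match(sample_ids, sample_meta$sample_id), ]
  rownames(sample_meta) <- NULL
  sample_meta$replicate <- as.integer(sample_meta$replicate)
  if (any(is.na(sample_meta$replicate)) || any(sample_meta$replicate < 1L))
    stop("replicate must be a positive integer")
  sample_meta$day <- as.numeric(sample_meta$day)
  if (any(is.na(sample_meta$day)) || any(sample_meta$day < 0))
    stop("day must be a nonnegative number")
  bad_role <- setdiff(unique(sample_meta$role), SAMPLE_ROLES)
  if (length(bad_role))
    stop("unknown sample role(s): ", paste(bad_role, collapse = ", "),
         " (expected one of ", paste(SAMPLE_ROLES, collapse = ", "), ")")
  sample_meta
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d elements x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat("conditions:", paste(unique(x$sample_meta$condition), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

## ---------------------------------------------------------------------------
## TSV I/O.  All tables are tab-separated UTF-8 with a header row; writers
## prepend '#'-comment header lines (version, parameters) which readers skip.
## ---------------------------------------------------------------------------

ns_header_lines <- function(params = list()) {
  ver <- as.character(utils::packageVersion("nutriscreen"))
  lines <- sprintf("# nutriscreen %s", ver)
  if (length(params)) {
    vals <- vapply(params, function(v) paste(format(v), collapse = ","), "")
    lines <- c(lines, sprintf("# %s: %s", names(params), vals))
  }
  lines
}

#' Write a data frame as a commented TSV
#'
#' Writers emit a deterministic column order, '#'-prefixed header lines
#' recording the package version and any parameters, and numeric columns
#' formatted to 6 significant digits.
#'
#' @param df data frame.
#' @param path output path.
#' @param params named list echoed into the comment header.
#' @export
write_tsv_commented <- function(df, path, params = list()) {
  df <- as.data.frame(df)
  num <- vapply(df, is.double, TRUE)
  df[num] <- lapply(df[num], function(x) signif(x, 6))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(ns_header_lines(params), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read a commented TSV written by this package
#' @param path file path.
#' @return data frame.
#' @export
read_tsv_commented <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, comment.char = "#", check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' Read an element-by-sample count table with its sample sheet
#'
#' The count table is a TSV whose first column is `element_id` and whose
#' remaining columns are integer counts, one per sample. Sample metadata
#' lives in a sidecar sample sheet (TSV with columns `sample_id`,
#' `condition`, `replicate`, `day`, `role`) rather than being encoded in
#' column names.
#'
#' @param path path to the count TSV.
#' @param samples path to the sample sheet TSV, or a data frame.
#' @return a [count_matrix()].
#' @export
read_counts <- function(path, samples) {
  tab <- read_tsv_commented(path)
  if (names(tab)[1L] != "element_id")
    stop("count table must have 'element_id' as its first column, got '",
         names(tab)[1L], "'")
  ids <- as.character(tab$element_id)
  body <- tab[, -1L, drop = FALSE]
  for (j in seq_along(body)) {
    v <- body[[j]]
    if (!is.numeric(v))
      stop("non-numeric count in column '", names(body)[j], "'")
    bad <- which(v < 0 | v != round(v))
    if (length(bad))
      stop(sprintf("invalid count at row '%s', column '%s' (value %s): counts must be nonnegative integers",
                   ids[bad[1L]], names(body)[j], format(v[bad[1L]])))
  }
  counts <- as.matrix(body)
  rownames(counts) <- ids
  if (is.character(samples) && length(samples) == 1L)
    samples <- read_tsv_commented(samples)
  count_matrix(counts, samples)
}

#' Write a count matrix (and optionally its sample sheet) to TSV
#' @param m a [count_matrix()].
#' @param path output path for the count table.
#' @param samples_path optional output path for the sample sheet.
#' @param params named list echoed into the comment header.
#' @export
write_counts <- function(m, path, samples_path = NULL, params = list()) {
  stopifnot(inherits(m, "count_matrix"))
  df <- data.frame(element_id = rownames(m$counts), m$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  con <- file(path, open = "wt", encoding = "UTF-8")
  writeLines(ns_header_lines(params), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  if (!is.null(samples_path))
    write_tsv_commented(m$sample_meta, samples_path, params)
  invisible(path)
}

#' Read a library map (element to gene, with element class)
#'
#' @param path TSV with columns `element_id`, `gene`, `class`
#'   (`targeting` or `control_noncutting`), or a data frame.
#' @return validated data frame.
#' @export
read_library_map <- function(path) {
  lib <- if (is.data.frame(path)) path else read_tsv_commented(path)
  req <- c("element_id", "gene", "class")
  miss <- setdiff(req, names(lib))
  if (length(miss))
    stop("library map missing column(s): ", paste(miss, collapse = ", "))
  lib <- lib[, req]
  lib$element_id <- as.character(lib$element_id)
  lib$gene <- as.character(lib$gene)
  if (anyDuplicated(lib$element_id))
    stop("duplicate element_id in library map")
  bad <- setdiff(unique(lib$class), ELEMENT_CLASSES)
  if (length(bad))
    stop("unknown element class(es): ", paste(bad, collapse = ", "))
  lib
}

# Library/counts consistency: scoring requires a bijection in both
# directions -- silently zero-filling or dropping elements hides library
# construction errors.
check_library_counts <- function(lib, m) {
  ids <- rownames(m$counts)
  missing_in_lib <- setdiff(ids, lib$element_id)
  if (length(missing_in_lib))
    stop("element(s) present in counts but absent from library map: ",
         paste(utils::head(missing_in_lib, 5L), collapse = ", "))
  missing_in_counts <- setdiff(lib$element_id, ids)
  if (length(missing_in_counts))
    stop("element(s) present in library map but absent from counts: ",
         paste(utils::head(missing_in_counts, 5L), collapse = ", "))
  invisible(TRUE)
}

#' Read a gene expression table (log2 FPKM)
#'
#' Expression values may be `-Inf` (zero FPKM); genes may also be
#' entirely absent, which downstream scoring treats as "no value".
#'
#' @param path TSV with columns `gene` and `log2_fpkm`, or a data frame.
#' @return data frame with character `gene` and numeric `log2_fpkm`.
#' @export
read_expression_table <- function(path) {
  expr <- if (is.data.frame(path)) path else read_tsv_commented(path)
  req <- c("gene", "log2_fpkm")
  miss <- setdiff(req, names(expr))
  if (length(miss))
    stop("expression table missing column(s): ", paste(miss, collapse = ", "))
  expr <- expr[, req]
  expr$gene <- as.character(expr$gene)
  expr$log2_fpkm <- as.numeric(expr$log2_fpkm)
  if (anyDuplicated(expr$gene)) stop("duplicate gene in expression table")
  if (any(is.nan(expr$log2_fpkm)))
    stop("expression values must be finite, -Inf, or absent (not NaN)")
  expr
}
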