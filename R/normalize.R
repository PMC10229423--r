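#' Normalize counts to log2 reads-per-million with a pseudocount
#'
#' Each count is scaled by its sample's total to reads per million and
#' log2-transformed with a pseudocount of 1:
#' \deqn{v = \log_2(\mathrm{reads} / \mathrm{total} \times 10^6 + 1)}
#' The pseudocount keeps zero counts at exactly 0 and attenuates fold
#' changes of very low-abundance elements. Per sample the identity
#' \eqn{\sum_e (2^{v_e} - 1) = 10^6} holds by construction.
#'
#' @param m a [count_matrix()]; every column total must be positive.
#' @return an object of class `norm_matrix`: list with `values` (same
#'   shape as the counts, log2 RPM) and the `sample_meta` carried over.
#' @export
normalize_log2_rpm <- function(m) {
  stopifnot(inherits(m, "count_matrix"))
  totals <- colSums(m$counts)
  if (any(totals == 0))
    stop("sample(s) with zero total counts cannot be normalized: ",
         paste(colnames(m$counts)[totals == 0], collapse = ", "))
  v <- log2(sweep(m$counts, 2L, totals, "/") * 1e6 + 1)
  structure(list(values = v, sample_meta = m$sample_meta),
            class = "norm_matrix")
}

#' @export
print.norm_matrix <- function(x, ...) {
  cat(sprintf("norm_matrix (log2 RPM + 1): %d elements x %d samples\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Per-element log2 fold change between two samples
#'
#' Element-wise difference of log2-normalized values, `sample` minus
#' `reference`. Antisymmetric: swapping the two arguments negates the
#' result.
#'
#' @param norm a `norm_matrix` from [normalize_log2_rpm()].
#' @param sample,reference sample ids (columns of `norm`).
#' @return named numeric vector, one value per element.
#' @export
log2_fold_change <- function(norm, sample, reference) {
  stopifnot(inherits(norm, "norm_matrix"))
  for (id in c(sample, reference))
    if (!id %in% colnames(norm$values))
      stop("unknown sample id: ", id)
  norm$values[, sample] - norm$values[, reference]
}
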