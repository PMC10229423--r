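#' Natural-abundance convolution matrix for carbon
#'
#' Builds the (n+1) x (n+1) lower-triangular matrix C that maps a true
#' mass isotopomer distribution (MID) to the measured one when each of
#' the n carbons not already tracer-labelled has probability `p` of
#' being a naturally occurring 13C:
#' \deqn{C_{ij} = \binom{n-j}{i-j} p^{i-j} (1-p)^{n-i}, \quad i \ge j}
#' (0-based isotopologue indices). Columns are binomial distributions
#' and sum to 1, so convolution conserves total signal:
#' `measured = C %*% true`.
#'
#' Only carbon is modelled; contributions from 15N/2H/17O/18O and
#' tracer impurity are outside this correction.
#'
#' @param n number of carbon atoms (>= 1).
#' @param p natural 13C abundance as a fraction (default 0.0107, the
#'   IUPAC representative value); must satisfy `0 <= p < 0.5`.
#' @return numeric matrix with dimnames `M0..Mn`.
#' @export
natural_abundance_matrix <- function(n, p = 0.0107) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n))
    stop("n must be a positive integer carbon count")
  if (p < 0 || p >= 0.5)
    stop("natural abundance p must satisfy 0 <= p < 0.5")
  C <- matrix(0, n + 1L, n + 1L)
  for (j in 0:n)
    C[(j:n) + 1L, j + 1L] <- stats::dbinom(0:(n - j), size = n - j, prob = p)
  dimnames(C) <- list(paste0("M", 0:n), paste0("M", 0:n))
  C
}

#' Correct a measured isotopologue vector for natural abundance
#'
#' Solves `C %*% x = raw / sum(raw)` for the tracer-derived MID `x`.
#' Method `"inverse"` is the exact triangular solve: it reproduces a
#' noiseless convolution to machine precision but can return small
#' negative fractions on noisy data. Method `"nnls"` (the default)
#' solves the nonnegative least-squares problem instead, guaranteeing
#' a proper distribution. Either way the result is renormalized to sum
#' to 1.
#'
#' @param raw numeric vector of raw intensities M0..Mn (length n+1,
#'   nonnegative, not all zero). Arbitrary units: the correction is
#'   scale-invariant.
#' @param n carbon count; defaults to `length(raw) - 1`.
#' @param p natural 13C abundance (default 0.0107).
#' @param method `"nnls"` (default) or `"inverse"`.
#' @return object of class `corrected_mid`: numeric vector of
#'   fractions M0..Mn summing to 1, with attributes `n`, `p`, `method`.
#' @export
correct_mid <- function(raw, n = length(raw) - 1L, p = 0.0107,
                        method = c("nnls", "inverse")) {
  method <- match.arg(method)
  raw <- as.numeric(raw)
  if (length(raw) != n + 1L)
    stop("raw must have length n + 1 = ", n + 1L, " (M0..Mn)")
  if (anyNA(raw) || any(raw < 0))
    stop("raw intensities must be nonnegative and non-missing")
  if (sum(raw) == 0) stop("all-zero intensity vector cannot be corrected")
  b <- raw / sum(raw)
  C <- natural_abundance_matrix(n, p)
  x <- switch(method,
    inverse = as.numeric(forwardsolve(C, b)),
    nnls = as.numeric(pracma::lsqnonneg(C, b)$x))
  s <- sum(x)
  if (s <= 0) stop("correction produced a nonpositive total; cannot renormalize")
  x <- x / s
  structure(stats::setNames(x, paste0("M", 0:n)),
            n = n, p = p, method = method, class = "corrected_mid")
}

#' Percentage of the pool carrying tracer label
#'
#' `100 * (1 - M0)` of a corrected MID: the percentage of 13C-labelled
#' molecules relative to the total pool.
#'
#' @param x a `corrected_mid` (or plain fraction vector M0..Mn).
#' @return percentage in `[0, 100]`.
#' @export
fraction_labeled <- function(x) {
  100 * (1 - as.numeric(x)[1L])
}

#' Mean fractional enrichment of a corrected MID
#'
#' `sum(i * M_i) / n`: the average fraction of carbon atoms that are
#' labelled. 0 for an unlabelled pool, 1 for a fully labelled one.
#'
#' @param x a `corrected_mid` (or plain fraction vector M0..Mn).
#' @return fraction in `[0, 1]`.
#' @export
mean_enrichment <- function(x) {
  v <- as.numeric(x)
  n <- length(v) - 1L
  sum((0:n) * v) / n
}

#' Correct a table of isotopologue measurements
#'
#' Input rows are metabolites with raw intensities in columns
#' `M0..Mn`; metabolites may have different carbon counts (columns
#' beyond a metabolite's Mn are `NA` or absent).
#'
#' @param mids data frame (or TSV path) with columns `metabolite`,
#'   `n_carbons`, `M0`, `M1`, ... .
#' @param p natural 13C abundance (default 0.0107).
#' @param method passed to [correct_mid()].
#' @return data frame with `metabolite`, `n_carbons`, corrected
#'   fractions `M0..Mn`, `fraction_labeled` (percent) and
#'   `mean_enrichment`.
#' @export
correct_mid_table <- function(mids, p = 0.0107,
                              method = c("nnls", "inverse")) {
  method <- match.arg(method)
  tab <- if (is.data.frame(mids)) mids else read_tsv_commented(mids)
  req <- c("metabolite", "n_carbons")
  if (!all(req %in% names(tab)))
    stop("MID table needs columns: ", paste(req, collapse = ", "))
  n_max <- max(tab$n_carbons)
  mcols <- paste0("M", 0:n_max)
  if (!all(mcols[1:2] %in% names(tab)))
    stop("MID table needs intensity columns M0, M1, ...")
  out <- lapply(seq_len(nrow(tab)), function(i) {
    n <- tab$n_carbons[i]
    raw <- as.numeric(tab[i, paste0("M", 0:n)])
    corr <- correct_mid(raw, n = n, p = p, method = method)
    row <- stats::setNames(rep(NA_real_, n_max + 1L), mcols)
    row[paste0("M", 0:n)] <- as.numeric(corr)
    data.frame(metabolite = tab$metabolite[i], n_carbons = n,
               as.list(row),
               fraction_labeled = fraction_labeled(corr),
               mean_enrichment = mean_enrichment(corr),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
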