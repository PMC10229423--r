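# Small in-code fixtures shared across test files.

toy_count_matrix <- function(counts = NULL, conditions = NULL) {
  if (is.null(counts)) {
    counts <- matrix(c(100L, 900L, 400L, 600L), 2, 2,
                     dimnames = list(c("EL1", "EL2"), c("s1", "s2")))
  }
  ids <- colnames(counts)
  if (is.null(conditions)) conditions <- rep("glucose", length(ids))
  count_matrix(counts, data.frame(
    sample_id = ids, condition = conditions,
    replicate = seq_along(ids), day = 21, role = "screen"))
}

# counts for a two-condition screen with nrep replicates per condition,
# one row per element of `mu` (exact expected counts, no noise)
exact_screen_matrix <- function(mu_a, mu_b, nrep = 2, day = 21,
                                conds = c("condA", "condB")) {
  stopifnot(length(mu_a) == length(mu_b))
  n <- length(mu_a)
  cols <- c(replicate(nrep, mu_a, simplify = FALSE),
            replicate(nrep, mu_b, simplify = FALSE))
  counts <- do.call(cbind, cols)
  ids <- c(paste0(conds[1], "_r", seq_len(nrep)),
           paste0(conds[2], "_r", seq_len(nrep)))
  dimnames(counts) <- list(paste0("EL", seq_len(n)), ids)
  count_matrix(counts, data.frame(
    sample_id = ids,
    condition = rep(conds, each = nrep),
    replicate = rep(seq_len(nrep), 2),
    day = day, role = "screen"))
}

# brute-force BH step-up, straight from the definition
bh_brute <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (idx in seq_len(m)) {
    i <- ord[idx]
    # q_i = min over j with p_j >= p_i of m * p_j / rank(p_j)
    cand <- vapply(seq_len(m), function(jdx) {
      j <- ord[jdx]
      if (jdx >= idx) m * p[j] / jdx else Inf
    }, 0)
    q[i] <- min(1, min(cand))
  }
  q
}
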