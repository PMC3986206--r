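# shared fixtures and independent oracles used across test files

# small genotype matrix from explicit calls (rows = accessions)
gm <- function(calls, ids = NULL, mk = NULL, het = NULL) {
  calls <- as.matrix(calls)
  if (is.null(ids)) {
    ids <- if (!is.null(rownames(calls))) rownames(calls) else
      sprintf("a%d", seq_len(nrow(calls)))
  }
  if (is.null(mk)) {
    mk <- if (!is.null(colnames(calls))) colnames(calls) else
      sprintf("m%d", seq_len(ncol(calls)))
  }
  rownames(calls) <- ids
  colnames(calls) <- mk
  if (!is.null(het)) dimnames(het) <- dimnames(calls)
  genotype_matrix(calls, het = het)
}

# the 4 x 3 worked example used for PIC and ranking checks
pic_example <- function() {
  gm(rbind(
    a1 = c(0, 0, 0),
    a2 = c(1, 1, 1),
    a3 = c(0, 1, 0),
    a4 = c(0, 0, 1)
  ), ids = c("a1", "a2", "a3", "a4"))
}

# naive full-recomputation PIC ranking oracle (no incremental updates)
naive_rank_accessions <- function(g, min_size = 2) {
  calls <- g$calls
  ids <- rownames(calls)
  avg_pic_of <- function(rows) {
    sub <- calls[rows, , drop = FALSE]
    n_obs <- colSums(!is.na(sub))
    p <- colSums(sub, na.rm = TRUE) / n_obs
    mean((2 * p * (1 - p))[n_obs > 0])
  }
  current <- ids
  removal <- character(0)
  traj <- avg_pic_of(current)
  while (length(current) > min_size) {
    pics <- vapply(current, function(a) avg_pic_of(setdiff(current, a)), numeric(1))
    best <- max(pics)
    tied <- sort(current[pics >= best - 1e-12])
    pick <- tied[1]
    removal <- c(removal, pick)
    current <- setdiff(current, pick)
    traj <- c(traj, best)
  }
  sizes <- seq(length(ids), min_size)
  list(
    removal_order = removal,
    trajectory = data.frame(size = sizes, avg_pic = traj),
    peak_size = sizes[which.max(traj)]
  )
}

# brute-force two-sided Fisher p (point-probability method) for a 2x2 table
fisher_oracle <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  a_obs <- tab[1, 1]
  a_all <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(a_all, r1, r2, c1)
  p_obs <- dhyper(a_obs, r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# brute-force BH step-up oracle
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- m * p[o] / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}
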