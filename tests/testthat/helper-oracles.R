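# Independent oracles and tiny fixture builders used across the suite.

# Brute-force Wilcoxon rank-sum p-value: enumerate every assignment of
# the pooled observations to the first sample (combn over indices) and
# count rank sums at least as extreme as the observed one. Independent of
# the package's DP-based exact path.
brute_force_wilcoxon <- function(x, y, alternative = "two-sided") {
  n1 <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n1)])
  splits <- utils::combn(length(pooled), n1)
  w_all <- apply(splits, 2, function(idx) sum(r[idx]))
  p_le <- mean(w_all <= w_obs)
  p_ge <- mean(w_all >= w_obs)
  switch(alternative,
    greater = p_ge,
    less = p_le,
    `two-sided` = min(1, 2 * min(p_le, p_ge))
  )
}

# Wide counts tibble + sample sheet from explicit replicate vectors
# (one protein per row of the bait/control matrices).
make_counts <- function(bait, ctrl, ids = NULL) {
  bait <- rbind(bait)
  ctrl <- rbind(ctrl)
  ids <- ids %||% sprintf("prot%02d", seq_len(nrow(bait)))
  counts <- tibble::tibble(protein_id = ids)
  for (j in seq_len(ncol(bait))) counts[[paste0("b", j)]] <- bait[, j]
  for (j in seq_len(ncol(ctrl))) counts[[paste0("c", j)]] <- ctrl[, j]
  samples <- tibble::tibble(
    sample_id = c(paste0("b", seq_len(ncol(bait))),
                  paste0("c", seq_len(ncol(ctrl)))),
    group = rep(c("bait", "control"), c(ncol(bait), ncol(ctrl))),
    replicate = c(seq_len(ncol(bait)), seq_len(ncol(ctrl)))
  )
  list(counts = counts, samples = samples)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
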