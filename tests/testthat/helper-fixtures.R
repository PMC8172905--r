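# Shared fixtures and small independent oracles.

# expression matrix with the 10 RSI genes (rows in signature order) plus
# optional background genes
rsi_matrix <- function(n_samples = 5, n_background = 0, seed = 1, sd = 1) {
  set.seed(seed)
  genes <- rsi_signature()$genes
  if (n_background > 0) genes <- c(genes, sprintf("BG%03d", seq_len(n_background)))
  matrix(rnorm(length(genes) * n_samples, mean = 5, sd = sd),
         nrow = length(genes),
         dimnames = list(genes, sprintf("s%03d", seq_len(n_samples))))
}

# all permutations of 1..n, one per row (insertion construction)
all_permutations <- function(n) {
  perms <- matrix(1L, 1, 1)
  if (n == 1) return(perms)
  for (m in 2:n) {
    out <- vector("list", m)
    for (pos in 1:m) {
      if (pos == 1L) out[[pos]] <- cbind(m, perms)
      else if (pos == m) out[[pos]] <- cbind(perms, m)
      else out[[pos]] <- cbind(perms[, 1:(pos - 1), drop = FALSE], m,
                               perms[, pos:(m - 1), drop = FALSE])
    }
    perms <- do.call(rbind, out)
  }
  perms
}

# independent unweighted KS walk (oracle for gsva_score with tau = 0):
# step up 1/k inside the set, down 1/(p-k) outside, genes in decreasing
# statistic order; score = max positive + min negative deviation
unweighted_ks_es <- function(stat_col, in_set) {
  p <- length(stat_col)
  k <- sum(in_set)
  ord <- order(stat_col, decreasing = TRUE)
  steps <- ifelse(in_set[ord], 1 / k, -1 / (p - k))
  v <- cumsum(steps)
  max(c(v, 0)) + min(c(v, 0))
}

# exponential survival fixture with a binary group effect
sim_survival <- function(n, rate_low = 0.1, hr = 2, p_high = 0.5,
                         cens_rate = 0.05, seed = 1) {
  set.seed(seed)
  high <- runif(n) < p_high
  t_ev <- rexp(n, rate = rate_low * hr^high)
  t_cn <- rexp(n, rate = cens_rate)
  data.frame(sample_id = sprintf("s%04d", seq_len(n)),
             time = pmin(t_ev, t_cn),
             event = as.integer(t_ev <= t_cn),
             group = ifelse(high, "high", "low"),
             x = as.numeric(high))
}
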