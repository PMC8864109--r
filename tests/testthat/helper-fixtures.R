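# Shared fixtures and independent oracles used across the suite.

# small two-group design: nA + nB samples
toy_design <- function(n_a = 4, n_b = 4, groups = c("Sham", "MI_CIH")) {
  group_design(
    sample_ids = c(sprintf("A%d", seq_len(n_a)), sprintf("B%d", seq_len(n_b))),
    groups = rep(groups, c(n_a, n_b)),
    group_levels = groups
  )
}

# single-group design for tests that only need sample columns
flat_design <- function(n) {
  group_design(sprintf("S%d", seq_len(n)), rep("G", n))
}

# expression matrix from explicit values (linear scale)
toy_matrix <- function(values, species = "mRNA", design = NULL) {
  if (is.null(design)) {
    design <- toy_design(ncol(values) / 2, ncol(values) / 2)
  }
  colnames(values) <- design$sample_ids
  expression_matrix(values, species, design)
}

# a small standard simulated dataset reused by several files
small_dataset <- function(seed = 7, ...) {
  simulate_dataset(sim_config(n_mrna = 300, n_mirna = 40, n_lncrna = 80,
                              hub_size = 40, seed = seed, ...))
}

# ---- independent oracles ----------------------------------------------------

# brute-force BH step-up from the definition: q_(i) = min_{j >= i} p_(j)*n/j
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, p[o] * n / seq_len(n))
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(n)
  q[o] <- q_sorted
  q
}

# two-sided Fisher p by explicit enumeration with factorial-based pmf
fisher_oracle <- function(k, K, n, N) {
  pmf <- function(x) {
    exp(lchoose(K, x) + lchoose(N - K, n - x) - lchoose(N, n))
  }
  support <- max(0, n + K - N):min(K, n)
  probs <- vapply(support, pmf, numeric(1))
  p_obs <- pmf(k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# Pearson r from the raw definition
pearson_oracle <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# degree recount by double loop over the edge list
degree_oracle <- function(net) {
  deg <- stats::setNames(integer(length(net$nodes)), names(net$nodes))
  for (i in seq_len(nrow(net$edges))) {
    s <- net$edges$source_id[i]; t <- net$edges$target_id[i]
    deg[s] <- deg[s] + 1L
    deg[t] <- deg[t] + 1L
  }
  deg
}

# re-verify every licensing condition of emitted triplets by direct
# correlation on the analysis (log2) scale
verify_triplets <- function(triplets, targets, lnc_mat, mir_mat, mrna_mat,
                            neg_cutoff, pos_cutoff) {
  lg <- function(m) log2(pmax(m$values, 2^-20))
  lx <- lg(lnc_mat); mx <- lg(mir_mat); gx <- lg(mrna_mat)
  ok <- logical(nrow(triplets))
  for (i in seq_len(nrow(triplets))) {
    l <- triplets$lncrna_id[i]; m <- triplets$mirna_id[i]
    g <- triplets$mrna_id[i]
    ok[i] <- g %in% targets$mirna_to_mrna[[m]] &&
      l %in% targets$mirna_to_lncrna[[m]] &&
      pearson_oracle(lx[l, ], mx[m, ]) <= -neg_cutoff &&
      pearson_oracle(gx[g, ], mx[m, ]) <= -neg_cutoff &&
      pearson_oracle(lx[l, ], gx[g, ]) >= pos_cutoff
  }
  ok
}

triplet_key <- function(l, m, g) paste(l, m, g, sep = "|")
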