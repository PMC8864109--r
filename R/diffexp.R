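# Moderated differential expression with the random variance model (RVM).
#
# Feature precisions are modelled as Gamma(a, scale b) across features
# (variances inverse-gamma). Under that prior the pooled residual variance
# s^2 with m degrees of freedom satisfies a*b*s^2 ~ F(m, 2a) marginally,
# which is the likelihood maximised by fit_rvm_prior(). The moderated
# variance is the convex combination (m*s^2 + 2/b) / (m + 2a) and the
# moderated t has m + 2a degrees of freedom.

#' Normalize an expression matrix
#'
#' `library_size` rescales every sample column so that all column sums equal
#' the median column sum of the input; `none` is the identity. The operation
#' is idempotent: renormalizing a normalized matrix changes nothing.
#'
#' @param matrix An [expression_matrix()].
#' @param method `"none"` or `"library_size"`.
#' @return A normalized [expression_matrix()].
#' @export
normalize_matrix <- function(matrix, method = c("none", "library_size")) {
  method <- match.arg(method)
  stopifnot(inherits(matrix, "expr_matrix"))
  if (method == "none") return(matrix)
  csums <- colSums(matrix$values)
  if (any(csums == 0)) {
    stop("empty sample: ", paste(colnames(matrix$values)[csums == 0],
                                 collapse = ", "), call. = FALSE)
  }
  target <- stats::median(csums)
  matrix$values <- sweep(matrix$values, 2, target / csums, `*`)
  matrix
}

group_pair_stats <- function(matrix, group_a, group_b) {
  design <- matrix$design
  if (!all(c(group_a, group_b) %in% design$groups)) {
    stop("group absent from design: ",
         paste(setdiff(c(group_a, group_b), design$groups), collapse = ", "),
         call. = FALSE)
  }
  sa <- design_samples(design, group_a)
  sb <- design_samples(design, group_b)
  if (length(sa) < 2 || length(sb) < 2) {
    stop("both groups need >= 2 samples", call. = FALSE)
  }
  la <- log2p1(matrix$values[, sa, drop = FALSE])
  lb <- log2p1(matrix$values[, sb, drop = FALSE])
  na <- length(sa); nb <- length(sb)
  ma <- rowMeans(la); mb <- rowMeans(lb)
  ssa <- rowSums((la - ma)^2)
  ssb <- rowSums((lb - mb)^2)
  list(
    na = na, nb = nb, m = na + nb - 2L,
    log_mean_a = ma, log_mean_b = mb,
    s2 = (ssa + ssb) / (na + nb - 2L),
    lin_mean_a = rowMeans(matrix$values[, sa, drop = FALSE]),
    lin_mean_b = rowMeans(matrix$values[, sb, drop = FALSE])
  )
}

#' Fit the RVM variance prior across features
#'
#' Computes each feature's pooled residual variance on log2(x+1) values for
#' the two groups (m = nA + nB - 2 residual df) and fits the gamma prior on
#' precisions, Gamma(a, scale b), by maximum likelihood using the marginal
#' relationship a*b*s2 ~ F(m, 2a). Zero-variance features are excluded from
#' the fit.
#'
#' @param matrix An [expression_matrix()].
#' @param group_a,group_b Group labels present in the design.
#' @return Object of class `rvm_prior`: fields `a`, `b`, `m`, `n_features`
#'   (used in the fit), `at_bound` (degenerate fit clamped at the
#'   optimization bound), `loglik`.
#' @export
fit_rvm_prior <- function(matrix, group_a, group_b) {
  st <- group_pair_stats(matrix, group_a, group_b)
  s2 <- st$s2[st$s2 > 0]
  if (length(s2) < 2) {
    stop("need >= 2 features with positive residual variance", call. = FALSE)
  }
  m <- st$m
  # method-of-moments initial values from E[F(m, 2a)] = a/(a-1) for a > 1
  a0 <- 2; b0 <- 1 / (a0 * mean(s2) * (a0 - 1) / a0)
  if (!is.finite(b0) || b0 <= 0) b0 <- 1 / mean(s2)

  negll <- function(par) {
    a <- exp(par[1]); b <- exp(par[2])
    -sum(log(a * b) + stats::df(a * b * s2, df1 = m, df2 = 2 * a, log = TRUE))
  }
  lower <- c(log(1e-3), log(1e-9))
  upper <- c(log(1e3), log(1e9))
  opt <- stats::optim(c(log(a0), log(b0)), negll, method = "L-BFGS-B",
                      lower = lower, upper = upper,
                      control = list(maxit = 500))
  a <- exp(opt$par[1]); b <- exp(opt$par[2])
  at_bound <- any(abs(opt$par - lower) < 1e-6) || any(abs(opt$par - upper) < 1e-6)
  if (opt$convergence != 0 && !at_bound) {
    stop(sprintf(
      "RVM prior fit did not converge (code %d, %s); a=%.4g b=%.4g nll=%.6g",
      opt$convergence, opt$message %||% "", a, b, opt$value), call. = FALSE)
  }
  structure(list(a = a, b = b, m = m, n_features = length(s2),
                 at_bound = at_bound, loglik = -opt$value),
            class = "rvm_prior")
}

#' @export
print.rvm_prior <- function(x, ...) {
  cat(sprintf("rvm_prior: a = %.4g, b = %.4g, m = %d (%d features%s)\n",
              x$a, x$b, x$m, x$n_features,
              if (x$at_bound) ", degenerate: at bound" else ""))
  invisible(x)
}

#' RVM moderated t-test between two groups
#'
#' Per feature, the moderated variance is
#' `(m * s2 + 2/b) / (m + 2a)` and the moderated t statistic is the log2
#' group-mean difference over its moderated standard error, with
#' `m + 2a` degrees of freedom. Setting `a = 0`, `b = Inf` removes the prior
#' and recovers the ordinary pooled-variance Student t exactly. Fold changes
#' are ratios of linear-scale group means (B over A).
#'
#' @param matrix An [expression_matrix()].
#' @param group_a,group_b Group labels (contrast is B vs A).
#' @param prior An [fit_rvm_prior()] result (or a list with `a`, `b`).
#' @return data.frame with columns feature_id, mean_A, mean_B, fold_change,
#'   t_mod, df_mod, p, q, passes (q is BH across all features; passes is NA
#'   until [filter_de()] sets it).
#' @export
rvm_t_test <- function(matrix, group_a, group_b, prior) {
  st <- group_pair_stats(matrix, group_a, group_b)
  a <- prior$a; b <- prior$b
  stopifnot(is.numeric(a), a >= 0, is.numeric(b), b > 0)
  if (!is.null(prior$m) && prior$m != st$m) {
    warning("prior residual df (", prior$m, ") differ from this contrast (",
            st$m, ")")
  }
  m <- st$m
  two_over_b <- if (is.infinite(b)) 0 else 2 / b
  df_mod <- m + 2 * a
  sigma2 <- (m * st$s2 + two_over_b) / df_mod
  delta <- st$log_mean_b - st$log_mean_a
  se <- sqrt(sigma2 * (1 / st$na + 1 / st$nb))
  t_mod <- ifelse(delta == 0, 0, delta / se)   # 0/0 -> 0 for flat features
  p <- ifelse(delta == 0, 1, 2 * stats::pt(-abs(t_mod), df = df_mod))
  data.frame(
    feature_id = names(st$s2) %||% rownames(matrix$values),
    mean_A = unname(st$lin_mean_a),
    mean_B = unname(st$lin_mean_b),
    fold_change = unname(st$lin_mean_b / st$lin_mean_a),
    t_mod = unname(t_mod),
    df_mod = df_mod,
    p = unname(p),
    q = bh_fdr(unname(p)),
    passes = NA,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Species-specific differential-expression thresholds
#'
#' Defaults used by the workflow: fold change >= 5 (mRNA), >= 30 (miRNA),
#' >= 1.5 (lncRNA), all at p < .05.
#'
#' @param species `"mRNA"`, `"miRNA"` or `"lncRNA"`.
#' @return list with `fc_min` and `p_max`.
#' @export
de_thresholds <- function(species = c("mRNA", "miRNA", "lncRNA")) {
  species <- match.arg(species)
  list(fc_min = switch(species, mRNA = 5, miRNA = 30, lncRNA = 1.5),
       p_max = 0.05)
}

#' Filter differential-expression results
#'
#' A feature passes iff `max(FC, 1/FC) >= fc_min` and `p < p_max`
#' (two-sided fold-change rule, so 10-fold down-regulation passes a 5-fold
#' cutoff). Set `one_sided = TRUE` for the literal `FC >= fc_min` reading,
#' or `use_q = TRUE` to filter on BH-adjusted q instead of raw p.
#'
#' @param results data.frame from [rvm_t_test()].
#' @param fc_min Fold-change cutoff (>= 1).
#' @param p_max Significance cutoff.
#' @param one_sided Only up-regulation counts if TRUE.
#' @param use_q Filter on `q` rather than `p`.
#' @return `results` with the logical `passes` column filled in.
#' @export
filter_de <- function(results, fc_min, p_max = 0.05, one_sided = FALSE,
                      use_q = FALSE) {
  stopifnot_scalar_number(fc_min, "fc_min", lower = 1)
  stopifnot_scalar_number(p_max, "p_max", lower = 0, upper = 1)
  fc <- results$fold_change
  fc_eff <- if (one_sided) fc else pmax(fc, 1 / fc)
  pv <- if (use_q) results$q else results$p
  results$passes <- fc_eff >= fc_min & pv < p_max
  results
}

de_feature_ids <- function(results) results$feature_id[which(results$passes)]

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate control with monotonicity enforcement;
#' preserves input order.
#'
#' @param pvalues Numeric vector in \[0, 1\].
#' @return q-values in the same order.
#' @export
bh_fdr <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Hierarchical clustering of (differential) features
#'
#' Rows are z-scored per feature on log2(x+1) values, then clustered
#' agglomeratively (default average linkage on Euclidean distance). Features
#' with zero variance are excluded with a warning. Rows enter in
#' lexicographic feature-id order so the leaf ordering is deterministic.
#'
#' @param matrix An [expression_matrix()].
#' @param feature_subset Feature ids to cluster (default all).
#' @param linkage Agglomeration method for [stats::hclust()].
#' @param metric `"euclidean"`, `"manhattan"`, or `"correlation"`
#'   (1 - Pearson r).
#' @return list with `order` (leaf ids left to right), `hclust` (the merge
#'   tree), and `excluded` (zero-variance features).
#' @export
cluster_features <- function(matrix, feature_subset = NULL,
                             linkage = c("average", "complete", "single",
                                         "ward.D2"),
                             metric = c("euclidean", "manhattan",
                                        "correlation")) {
  linkage <- match.arg(linkage)
  metric <- match.arg(metric)
  stopifnot(inherits(matrix, "expr_matrix"))
  feats <- feature_subset %||% rownames(matrix$values)
  missing <- setdiff(feats, rownames(matrix$values))
  if (length(missing)) {
    stop("unknown features: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  feats <- sort_ids(unique(feats))
  x <- log2p1(matrix$values[feats, , drop = FALSE])
  sds <- apply(x, 1, stats::sd)
  excluded <- feats[sds == 0]
  if (length(excluded)) {
    warning("excluding zero-variance feature(s): ",
            paste(excluded, collapse = ", "))
    x <- x[sds > 0, , drop = FALSE]
  }
  if (nrow(x) < 2) stop("need >= 2 features with variance", call. = FALSE)
  z <- t(scale(t(x)))
  d <- if (metric == "correlation") {
    stats::as.dist(1 - stats::cor(t(z)))
  } else {
    stats::dist(z, method = metric)
  }
  hc <- stats::hclust(d, method = linkage)
  list(order = rownames(z)[hc$order], hclust = hc, excluded = excluded)
}

#' Relative expression by the 2^-ddCt method
#'
#' `dCt_sample = ct_target_sample - ct_ref_sample`,
#' `dCt_cal = ct_target_calibrator - ct_ref_calibrator`, and the relative
#' expression is `2^-(dCt_sample - dCt_cal)` (reference gene e.g. 18S rRNA).
#'
#' @param ct_target_sample,ct_ref_sample,ct_target_calibrator,ct_ref_calibrator
#'   Cycle-threshold values (vectorized).
#' @return Relative expression level(s).
#' @export
ddct <- function(ct_target_sample, ct_ref_sample,
                 ct_target_calibrator, ct_ref_calibrator) {
  cts <- cbind(ct_target_sample, ct_ref_sample,
               ct_target_calibrator, ct_ref_calibrator)
  if (any(!is.finite(cts))) stop("Ct values must be finite", call. = FALSE)
  d_sample <- ct_target_sample - ct_ref_sample
  d_cal <- ct_target_calibrator - ct_ref_calibrator
  2^-(d_sample - d_cal)
}
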