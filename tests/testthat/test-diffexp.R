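test_that("library-size normalization hits the median column sum and is idempotent", {
  vals <- matrix(c(40, 60, 150, 50, 40, 60, 100, 50), nrow = 4)
  rownames(vals) <- paste0("g", 1:4)
  m <- toy_matrix(vals, design = flat_design(2))
  expect_identical(normalize_matrix(m, "none")$values, m$values)
  norm <- normalize_matrix(m, "library_size")
  expect_equal(unname(colSums(norm$values)), c(275, 275))
  norm2 <- normalize_matrix(norm, "library_size")
  expect_equal(norm$values, norm2$values, tolerance = 1e-12)

  # hand case: sums 100 and 200 scale to the median 150
  vals2 <- matrix(c(100, 200), nrow = 1, dimnames = list("g1", NULL))
  m2 <- toy_matrix(vals2, design = flat_design(2))
  expect_equal(unname(colSums(normalize_matrix(m2, "library_size")$values)),
               c(150, 150))

  vals3 <- vals; vals3[, 2] <- 0
  m3 <- toy_matrix(vals3, design = flat_design(2))
  expect_error(normalize_matrix(m3, "library_size"), "empty sample")
})

test_that("prior fit recovers known parameters and is order-invariant", {
  # variances simulated straight from the model: precision ~ Gamma(2, 0.5)
  set.seed(123)
  n <- 10000; m <- 14; a_true <- 2; b_true <- 0.5
  sigma2 <- 1 / rgamma(n, shape = a_true, scale = b_true)
  design <- toy_design(8, 8)
  x <- matrix(rnorm(n * 16), nrow = n) * sqrt(sigma2) + 12
  rownames(x) <- sprintf("g%05d", seq_len(n))
  mat <- toy_matrix(2^x, design = design)
  pr <- fit_rvm_prior(mat, "Sham", "MI_CIH")
  expect_identical(pr$m, 14L)
  expect_lt(abs(pr$a - a_true) / a_true, 0.15)
  expect_lt(abs(pr$b - b_true) / b_true, 0.15)

  perm <- sample(n)
  mat_perm <- toy_matrix(2^x[perm, ], design = design)
  pr2 <- fit_rvm_prior(mat_perm, "Sham", "MI_CIH")
  expect_equal(pr$a, pr2$a, tolerance = 1e-8)
  expect_equal(pr$b, pr2$b, tolerance = 1e-8)
})

test_that("a degenerate constant-variance fit returns a finite flagged prior", {
  set.seed(5)
  design <- toy_design(4, 4)
  base <- matrix(rnorm(8), nrow = 1)
  x <- base[rep(1, 50), ] + 10
  rownames(x) <- sprintf("g%02d", 1:50)
  mat <- toy_matrix(2^x - 1, design = design)   # identical residual variance
  pr <- fit_rvm_prior(mat, "Sham", "MI_CIH")
  expect_true(is.finite(pr$a) && is.finite(pr$b))
  expect_true(pr$at_bound)
})

test_that("the moderated test has exact null and Student-t limiting behaviour", {
  design <- toy_design(3, 3)
  vals <- matrix(c(4, 8, 16, 4, 8, 16), nrow = 1)
  vals <- rbind(vals, matrix(runif(6 * 5, 10, 20), nrow = 5))
  rownames(vals) <- paste0("g", 1:6)
  mat <- toy_matrix(vals, design = design)
  prior <- list(a = 1, b = 2, m = 4)
  res <- rvm_t_test(mat, "Sham", "MI_CIH", prior)
  # identical values in both groups -> t = 0, p = 1
  expect_identical(res$t_mod[1], 0)
  expect_identical(res$p[1], 1)

  # prior weight removed -> ordinary pooled-variance Student t
  set.seed(77)
  design8 <- toy_design(8, 8)
  x <- matrix(rnorm(1000 * 16, mean = 9, sd = 1.3), nrow = 1000)
  rownames(x) <- sprintf("g%04d", seq_len(1000))
  mat8 <- toy_matrix(2^x - 1, design = design8)
  res0 <- rvm_t_test(mat8, "Sham", "MI_CIH", list(a = 0, b = Inf, m = 14))
  expect_true(all(res0$df_mod == 14))
  tstud <- apply(x, 1, function(v) {
    stats::t.test(v[9:16], v[1:8], var.equal = TRUE)$statistic
  })
  expect_lt(max(abs(res0$t_mod - tstud)), 1e-10)
})

test_that("moderated variance lies between s2 and the prior variance point", {
  set.seed(42)
  design <- toy_design(5, 5)
  x <- matrix(rnorm(200 * 10, 8, 2), nrow = 200)
  rownames(x) <- sprintf("g%03d", 1:200)
  mat <- toy_matrix(2^x - 1, design = design)
  pr <- fit_rvm_prior(mat, "Sham", "MI_CIH")
  st <- cernet:::group_pair_stats(mat, "Sham", "MI_CIH")
  sigma2 <- (st$m * st$s2 + 2 / pr$b) / (st$m + 2 * pr$a)
  prior_point <- 1 / (pr$a * pr$b)
  expect_true(all(sigma2 >= pmin(st$s2, prior_point) - 1e-12))
  expect_true(all(sigma2 <= pmax(st$s2, prior_point) + 1e-12))
})

test_that("the DE filter applies the two-sided fold-change rule", {
  res <- data.frame(
    feature_id = paste0("g", 1:5),
    fold_change = c(1.2, 1.6, 5.2, 0.5, 3.0),
    p = c(.01, .01, .2, .01, .04),
    q = c(.01, .01, .2, .01, .04)
  )
  out <- filter_de(res, fc_min = 1.5, p_max = 0.05)
  expect_identical(out$feature_id[out$passes], c("g2", "g4", "g5"))

  # strong down-regulation passes a 5-fold cutoff
  one <- data.frame(feature_id = "g", fold_change = 0.1, p = .01, q = .01)
  expect_true(filter_de(one, fc_min = 5)$passes)
  expect_false(filter_de(one, fc_min = 5, one_sided = TRUE)$passes)

  # vacuous filter keeps everything with p < 1
  expect_true(all(filter_de(res, fc_min = 1, p_max = 1)$passes))
  expect_error(filter_de(res, fc_min = 0.5), "fc_min")
  # output invariant to row order
  perm <- c(3, 1, 5, 2, 4)
  out_perm <- filter_de(res[perm, ], fc_min = 1.5, p_max = 0.05)
  expect_setequal(out_perm$feature_id[out_perm$passes],
                  out$feature_id[out$passes])
})

test_that("species default thresholds match the workflow's filters", {
  expect_identical(de_thresholds("mRNA")$fc_min, 5)
  expect_identical(de_thresholds("miRNA")$fc_min, 30)
  expect_identical(de_thresholds("lncRNA")$fc_min, 1.5)
})

test_that("BH q-values match the step-up definition", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_identical(bh_fdr(0.2), 0.2)
  set.seed(11)
  for (i in 1:25) {
    p <- runif(sample(1:50, 1))
    q <- bh_fdr(p)
    expect_equal(q, bh_oracle(p), tolerance = 1e-12)
    # monotone in p-rank
    expect_true(all(diff(q[order(p)]) >= -1e-12))
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("hierarchical clustering merges look right and are deterministic", {
  design <- toy_design(3, 3)
  base <- c(1, 2, 3, 4, 5, 6)
  vals <- rbind(
    g1 = 2^base, g2 = 2^base,                            # identical profiles
    g3 = 2^rev(base), g4 = 2^c(1, 2, 3, 4, 5, 7.5)       # g4 tracks g1/g2
  )
  mat <- toy_matrix(vals, design = design)
  cl <- cluster_features(mat)
  h <- cl$hclust
  feats <- sort(rownames(vals))
  expect_identical(feats[sort(-h$merge[1, ])], c("g1", "g2"))  # identical pair first
  expect_lt(h$height[1], 1e-10)
  # correlated pair merges before the anti-correlated profile joins
  three <- cluster_features(mat, c("g1", "g3", "g4"))
  expect_identical(c("g1", "g3", "g4")[sort(-three$hclust$merge[1, ])],
                   c("g1", "g4"))
  # stable leaf order across runs
  expect_identical(cl$order, cluster_features(mat)$order)
  # zero-variance features excluded with warning
  vals2 <- rbind(vals, g5 = rep(4, 6))
  expect_warning(cl2 <- cluster_features(toy_matrix(vals2, design = design)),
                 "zero-variance")
  expect_false("g5" %in% cl2$order)
})

test_that("ddct reproduces hand-computed relative expression", {
  expect_identical(ddct(20, 15, 22, 17), 1)          # ddCt = 0
  expect_identical(ddct(24, 18, 26, 18), 4)          # ddCt = -2
  expect_identical(ddct(26, 18, 24, 18), 0.25)       # ddCt = +2
  expect_error(ddct(NA, 1, 1, 1), "finite")
})
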