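# deterministic three-feature fixture with exact correlations: the miRNA is
# a decreasing profile, lncRNA/mRNA are increasing (r = -1 / +1 exactly on
# log scale)
exact_triplet_mats <- function(r_lnc = NULL) {
  design <- toy_design(3, 3)
  base <- c(1, 2, 3, 4, 5, 6)
  lnc <- rbind(l1 = 2^base, l2 = 2^c(6, 1, 5, 2, 4, 3))
  mir <- rbind(m1 = 2^rev(base))
  gx <- rbind(g1 = 2^(base * 2), g2 = 2^c(5, 1, 6, 2, 4, 3))
  list(
    lnc = toy_matrix(lnc, "lncRNA", design),
    mir = toy_matrix(mir, "miRNA", design),
    mrna = toy_matrix(gx, "mRNA", design)
  )
}

test_that("an empty target map yields no triplets", {
  mats <- exact_triplet_mats()
  out <- find_triplets(target_map(), mats$lnc, mats$mir, mats$mrna,
                       de_only = FALSE)
  expect_identical(nrow(out), 0L)
})

test_that("licensing conditions are enforced exactly", {
  mats <- exact_triplet_mats()
  tm <- target_map(mirna_to_mrna = list(m1 = c("g1", "g2")),
                   mirna_to_lncrna = list(m1 = c("l1", "l2")))
  out <- find_triplets(tm, mats$lnc, mats$mir, mats$mrna, de_only = FALSE)
  # only (l1, m1, g1) has r(l,m) = -1, r(g,m) = -1, r(l,g) = +1
  expect_identical(nrow(out), 1L)
  expect_identical(out$lncrna_id, "l1")
  expect_identical(out$mrna_id, "g1")
  expect_equal(out$r_lnc_mir, -1, tolerance = 1e-12)
  expect_equal(out$r_lnc_mrna, 1, tolerance = 1e-12)

  # a lncRNA-miRNA correlation weaker than the cutoff excludes the triplet
  design <- toy_design(4, 4)
  set.seed(61)
  z <- rnorm(8)
  lnc2 <- rbind(l1 = 2^(5 + z + rnorm(8, sd = 1.05)))   # |r| ~ 0.65
  mir2 <- rbind(m1 = 2^(5 - z))
  g2 <- rbind(g1 = 2^(5 + z + rnorm(8, sd = 0.05)))
  r_weak <- pearson_oracle(log2(lnc2[1, ]), log2(mir2[1, ]))
  expect_gt(r_weak, -0.7)   # genuinely above the negative cutoff
  out2 <- find_triplets(target_map(mirna_to_mrna = list(m1 = "g1"),
                                   mirna_to_lncrna = list(m1 = "l1")),
                        toy_matrix(lnc2, "lncRNA", design),
                        toy_matrix(mir2, "miRNA", design),
                        toy_matrix(g2, "mRNA", design),
                        neg_cutoff = 0.7, de_only = FALSE)
  expect_identical(nrow(out2), 0L)
})

test_that("planted triplets are recovered exactly and verify by brute force", {
  for (seed in 1:5) {
    ds <- simulate_dataset(sim_config(n_mrna = 300, n_mirna = 40, n_lncrna = 60,
                                      n_triplets = 10,
                                      triplet_corr_strength = 0.95,
                                      decoy_factor = 5, hub_size = 30,
                                      seed = seed))
    out <- find_triplets(ds$targets, ds$lncrna, ds$mirna, ds$mrna,
                         neg_cutoff = 0.7, pos_cutoff = 0.7, de_only = FALSE)
    truth <- ds$truth$planted_triplets
    truth_keys <- triplet_key(truth$lncrna, truth$mirna, truth$mrna)
    found_keys <- triplet_key(out$lncrna_id, out$mirna_id, out$mrna_id)
    expect_identical(mean(truth_keys %in% found_keys), 1)      # sensitivity 1
    expect_identical(setdiff(found_keys, truth_keys), character(0))
    expect_true(all(verify_triplets(out, ds$targets, ds$lncrna, ds$mirna,
                                    ds$mrna, 0.7, 0.7)))
  }
})

test_that("triplet search is invariant to row order and sample permutation", {
  ds <- simulate_dataset(sim_config(n_mrna = 200, n_mirna = 30, n_lncrna = 40,
                                    n_triplets = 6, hub_size = 20, seed = 33))
  base <- find_triplets(ds$targets, ds$lncrna, ds$mirna, ds$mrna,
                        de_only = FALSE)
  scramble <- function(mat, perm_samples) {
    v <- mat$values[sample(nrow(mat$values)), perm_samples, drop = FALSE]
    expression_matrix(v, mat$species, mat$design)
  }
  set.seed(44)
  perm <- sample(colnames(ds$mrna$values))
  out <- find_triplets(ds$targets, scramble(ds$lncrna, perm),
                       scramble(ds$mirna, perm), scramble(ds$mrna, perm),
                       de_only = FALSE)
  expect_equal(base, out, tolerance = 1e-12)
})

test_that("raising either cutoff never adds a triplet", {
  ds <- simulate_dataset(sim_config(n_mrna = 200, n_mirna = 30, n_lncrna = 40,
                                    n_triplets = 8, hub_size = 20,
                                    triplet_corr_strength = 0.8, seed = 13))
  keys <- function(neg, pos) {
    out <- find_triplets(ds$targets, ds$lncrna, ds$mirna, ds$mrna,
                         neg_cutoff = neg, pos_cutoff = pos, de_only = FALSE)
    triplet_key(out$lncrna_id, out$mirna_id, out$mrna_id)
  }
  loose <- keys(0.3, 0.3)
  expect_true(all(keys(0.6, 0.3) %in% loose))
  expect_true(all(keys(0.3, 0.6) %in% loose))
  expect_true(all(keys(0.8, 0.8) %in% keys(0.6, 0.6)))
})

test_that("the ceRNA network counts nodes, edges and degrees correctly", {
  one <- data.frame(lncrna_id = "l1", mirna_id = "m1", mrna_id = "g1",
                    r_lnc_mir = -0.9, r_mrna_mir = -0.9, r_lnc_mrna = 0.9)
  net1 <- build_cerna_network(one)
  expect_identical(length(net1$nodes), 3L)
  expect_identical(nrow(net1$edges), 2L)
  expect_identical(unname(net1$degree["m1"]), 2L)

  two <- rbind(one, data.frame(lncrna_id = "l2", mirna_id = "m1",
                               mrna_id = "g2", r_lnc_mir = -0.8,
                               r_mrna_mir = -0.8, r_lnc_mrna = 0.8))
  net2 <- build_cerna_network(two)
  expect_identical(unname(net2$degree["m1"]), 4L)
  expect_identical(sum(net2$class_counts), length(net2$nodes))
  expect_identical(net2$degree, degree_oracle(net2))
})

test_that("ceRNA hub ranking follows degree with id tie-breaks", {
  # one lncRNA in many triplets dominates
  reps <- data.frame(
    lncrna_id = c(rep("l_hub", 8), "l_a"),
    mirna_id = sprintf("m%d", c(1:8, 9)),
    mrna_id = sprintf("g%d", c(1:8, 9)),
    r_lnc_mir = -0.9, r_mrna_mir = -0.9, r_lnc_mrna = 0.9
  )
  net <- build_cerna_network(reps)
  hubs <- rank_cerna_hubs(net)
  expect_identical(hubs$id[hubs$class == "lncRNA" & hubs$is_hub], "l_hub")
  expect_identical(hubs$degree[hubs$id == "l_hub"], 8L)
  # all-equal degrees -> lexicographically first id wins
  ties <- data.frame(lncrna_id = c("lb", "la"), mirna_id = c("m1", "m2"),
                     mrna_id = c("g1", "g2"), r_lnc_mir = -0.9,
                     r_mrna_mir = -0.9, r_lnc_mrna = 0.9)
  hub_tie <- rank_cerna_hubs(build_cerna_network(ties))
  lnc_rows <- hub_tie[hub_tie$class == "lncRNA", ]
  expect_identical(lnc_rows$id[lnc_rows$is_hub], "la")
  # empty network -> empty ranking
  empty <- build_cerna_network(reps[0, ])
  expect_identical(nrow(rank_cerna_hubs(empty)), 0L)
})
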