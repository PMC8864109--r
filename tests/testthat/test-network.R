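test_that("correlate reproduces hand-computed Pearson coefficients", {
  design <- toy_design(2, 2)
  set.seed(3)
  a <- matrix(runif(5 * 4, 1, 50), nrow = 5,
              dimnames = list(paste0("l", 1:5), NULL))
  b <- matrix(runif(5 * 4, 1, 50), nrow = 5,
              dimnames = list(paste0("m", 1:5), NULL))
  ma <- toy_matrix(a, species = "lncRNA", design = design)
  mb <- toy_matrix(b, species = "mRNA", design = design)
  edges <- correlate(ma, mb, log_scale = FALSE)
  expect_identical(nrow(edges), 25L)
  for (i in seq_len(nrow(edges))) {
    expect_equal(edges$r[i],
                 pearson_oracle(a[edges$source_id[i], ],
                                b[edges$target_id[i], ]),
                 tolerance = 1e-12)
  }
  # self profile planted in both matrices -> r = 1; negated profile -> r = -1
  b2 <- rbind(m_same = a["l1", ], m_neg = max(a["l1", ]) + 1 - a["l1", ])
  mb2 <- toy_matrix(b2, species = "mRNA", design = design)
  e2 <- correlate(ma, mb2, features_a = "l1", log_scale = FALSE)
  expect_equal(e2$r[e2$target_id == "m_same"], 1, tolerance = 1e-12)
  expect_equal(e2$r[e2$target_id == "m_neg"], -1, tolerance = 1e-12)
})

test_that("correlate is symmetric and rejects tiny sample overlap", {
  design <- toy_design(3, 3)
  set.seed(8)
  a <- matrix(runif(12, 1, 9), nrow = 2, dimnames = list(c("l1", "l2"), NULL))
  b <- matrix(runif(18, 1, 9), nrow = 3, dimnames = list(paste0("m", 1:3), NULL))
  ma <- toy_matrix(a, "lncRNA", design); mb <- toy_matrix(b, "mRNA", design)
  e1 <- correlate(ma, mb)
  e2 <- correlate(mb, ma)
  key1 <- paste(e1$source_id, e1$target_id)
  key2 <- paste(e2$target_id, e2$source_id)
  expect_equal(e1$r, e2$r[match(key1, key2)], tolerance = 1e-14)

  d2 <- group_design(c("s1", "s2", "s3", "s4"), rep(c("A", "B"), 2))
  tiny_a <- expression_matrix(matrix(1:8, 2, 4,
                                     dimnames = list(c("x", "y"),
                                                     c("s1", "s2", "s3", "s4"))),
                              "lncRNA", d2)
  tiny_b <- expression_matrix(matrix(1:8, 2, 4,
                                     dimnames = list(c("u", "v"),
                                                     c("s5", "s6", "s3", "s4"))),
                              "mRNA",
                              group_design(c("s5", "s6", "s3", "s4"),
                                           rep(c("A", "B"), 2)))
  expect_error(correlate(tiny_a, tiny_b), "3 shared samples")
})

test_that("build_network filters on |r|, keeps signs, and satisfies the handshake lemma", {
  edges <- data.frame(
    source_id = c("l1", "l2", "l3"), source_class = "lncRNA",
    target_id = c("m1", "m1", "m2"), target_class = "mRNA",
    r = c(0.995, -0.992, 0.5), p_r = 0
  )
  net <- build_network(edges, r_cutoff = 0.99)
  expect_identical(nrow(net$edges), 2L)
  expect_true(-0.992 %in% net$edges$r)          # negative edge kept with sign
  expect_identical(sum(net$degree), 2L * nrow(net$edges))
  expect_identical(unname(net$degree["m1"]), 2L)

  # monotone: raising the cutoff never adds an edge
  set.seed(14)
  rnd <- data.frame(source_id = sprintf("l%02d", 1:40), source_class = "lncRNA",
                    target_id = sprintf("m%02d", sample(40)),
                    target_class = "mRNA",
                    r = runif(40, -1, 1), p_r = 0)
  cuts <- c(0.2, 0.5, 0.8, 0.95)
  sizes <- vapply(cuts, function(ct) nrow(build_network(rnd, ct)$edges),
                  numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("degrees equal a brute-force recount on simulated networks", {
  ds <- small_dataset(seed = 19)
  edges <- suppressWarnings(correlate(ds$lncrna, ds$mrna))
  net <- build_network(edges, r_cutoff = 0.9)
  expect_identical(net$degree, degree_oracle(net))
})

test_that("hub selection ranks by degree with deterministic ties", {
  star <- data.frame(
    source_id = rep("hub", 99), source_class = "lncRNA",
    target_id = sprintf("m%03d", 1:99), target_class = "mRNA",
    r = 1, p_r = 0
  )
  net <- build_network(star, 0.99)
  hubs <- select_hubs(net, "lncRNA", min_degree = 80)
  expect_identical(hubs$id, "hub")
  expect_identical(hubs$degree, 99L)
  expect_identical(nrow(select_hubs(net, "lncRNA", min_degree = 99)), 0L)
  # tie-break by id ascending
  ties <- data.frame(source_id = c("lb", "la"), source_class = "lncRNA",
                     target_id = c("m1", "m2"), target_class = "mRNA",
                     r = 1, p_r = 0)
  ranked <- select_hubs(build_network(ties, 0.5), "lncRNA")
  expect_identical(ranked$id, c("la", "lb"))
})

test_that("planted hubs are recovered with full degree and quiet background", {
  ds <- simulate_dataset(sim_config(n_mrna = 400, n_mirna = 30, n_lncrna = 60,
                                    n_hubs = 2, hub_size = 50, n_triplets = 5,
                                    seed = 23))
  de <- ds$truth$de_features
  edges <- suppressWarnings(correlate(ds$lncrna, ds$mrna,
                                      features_a = de$lncRNA,
                                      features_b = de$mRNA))
  net <- build_network(edges, 0.99)
  planted <- sort(grep("^lnc", names(ds$truth$hub_members), value = TRUE))
  hubs <- select_hubs(net, "lncRNA", min_degree = 40)
  expect_identical(sort(hubs$id), planted)        # 100% hub recall
  expect_identical(hubs$degree, c(50L, 50L))
  background <- setdiff(names(net$nodes)[unname(net$nodes) == "lncRNA"], planted)
  expect_true(all(net$degree[background] <= 40))
})

test_that("the pathway projection links regulators through annotated partners", {
  ann <- gene_set_collection(
    sets = list(t1 = c("m1", "m9"), t2 = c("m2"), t3 = c("m3", "m4"),
                t4 = c("m8")),
    universe = sprintf("m%d", 1:9)
  )
  sig <- data.frame(term_id = c("t1", "t2", "t3"), q = 0.01)
  edges <- data.frame(
    source_id = c("l1", "l1", "l1", "l2"), source_class = "lncRNA",
    target_id = c("m1", "m2", "m3", "m8"), target_class = "mRNA",
    r = 0.999, p_r = 0
  )
  net <- build_network(edges, 0.9)
  tp <- target_pathway_network(net, sig, ann)
  # l1's partners cover 3 significant terms
  expect_identical(unname(tp$degree["l1"]), 3L)
  # l2's only partner is in a non-significant term -> absent
  expect_false("l2" %in% names(tp$nodes))
  # pathway degree equals distinct-regulator recount
  expect_identical(tp$degree, degree_oracle(tp))
  expect_identical(unname(tp$nodes[c("t1", "t2", "t3")]),
                   rep("pathway", 3))
})
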