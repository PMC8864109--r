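# Multi-omic expression simulator with planted ground truth.
#
# The generator works on log2 scale: baseline feature means ~ Normal(6, 2),
# feature precisions ~ Gamma(rvm_a, scale rvm_b) (so variances are
# inverse-gamma and the RVM prior is recoverable), Gaussian noise, and the
# emitted linear-scale abundance is 2^value. Differential features get an
# additive log2 effect in the contrast group; hubs and ceRNA triplets are
# built from shared latent factors.

# within-group correlation of a planted hub with each of its partners
HUB_CORR <- 0.998

#' Simulation configuration
#'
#' Defaults emulate a four-arm rodent cardiac profiling study (Sham, CIH, MI,
#' MI_CIH; 8 replicates per arm) at reduced feature scale, with effect sizes
#' on the fold-change scales the downstream filters expect (mRNA ~8-fold,
#' miRNA ~54-fold, lncRNA ~4-fold).
#'
#' @param n_mrna,n_mirna,n_lncrna Feature counts per species.
#' @param n_reps Replicates per group (>= 2).
#' @param groups Ordered group labels; the last is the affected (contrast)
#'   group that receives the planted effects.
#' @param rvm_a,rvm_b Shape and scale of the gamma prior on feature
#'   precisions (variances are inverse-gamma).
#' @param de_fraction Per-species fraction of differential features, named
#'   numeric over mRNA/miRNA/lncRNA (a scalar is recycled). A species with
#'   fraction 0 gets no planted effects at all.
#' @param effect_log2fc Per-species absolute log2 fold change planted in the
#'   contrast group (named as `de_fraction`).
#' @param n_hubs Number of planted co-expression hubs per regulator species
#'   (that many lncRNA hubs and that many miRNA hubs).
#' @param hub_size mRNA partners per hub.
#' @param n_triplets Number of planted ceRNA (lncRNA, miRNA, mRNA) triplets.
#' @param triplet_corr_strength Within-group pairwise correlation magnitude
#'   of planted triplet members, in (0, 1].
#' @param decoy_factor Decoy target-map pairs per planted pair.
#' @param n_gene_sets Random annotation sets emitted in the GMT.
#' @param seed Integer seed driving all randomness.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_mrna = 1000, n_mirna = 80, n_lncrna = 200,
                       n_reps = 8,
                       groups = c("Sham", "CIH", "MI", "MI_CIH"),
                       rvm_a = 2, rvm_b = 0.5,
                       de_fraction = c(mRNA = 0.25, miRNA = 0.10, lncRNA = 0.15),
                       effect_log2fc = c(mRNA = 3, miRNA = 5.75, lncRNA = 2),
                       n_hubs = 2, hub_size = 100,
                       n_triplets = 10, triplet_corr_strength = 0.95,
                       decoy_factor = 5,
                       n_gene_sets = 20,
                       seed = 1) {
  species <- c("mRNA", "miRNA", "lncRNA")
  as_species_vec <- function(x, name) {
    if (length(x) == 1L && is.null(names(x))) x <- stats::setNames(rep(x, 3), species)
    if (!all(species %in% names(x))) {
      stop("`", name, "` must be named over mRNA/miRNA/lncRNA", call. = FALSE)
    }
    x[species]
  }
  de_fraction <- as_species_vec(de_fraction, "de_fraction")
  effect_log2fc <- as_species_vec(effect_log2fc, "effect_log2fc")

  for (nm in c("n_mrna", "n_mirna", "n_lncrna")) {
    stopifnot_scalar_number(get(nm), nm, lower = 1)
  }
  stopifnot_scalar_number(n_reps, "n_reps", lower = 0)
  if (n_reps < 2) stop("n_reps < 2: variance undefined", call. = FALSE)
  stopifnot_scalar_number(rvm_a, "rvm_a", lower = 1e-8)
  stopifnot_scalar_number(rvm_b, "rvm_b", lower = 1e-8)
  if (any(de_fraction < 0 | de_fraction > 1)) {
    stop("de_fraction must lie in [0, 1]", call. = FALSE)
  }
  stopifnot_scalar_number(n_hubs, "n_hubs", lower = 0)
  stopifnot_scalar_number(hub_size, "hub_size", lower = 0)
  stopifnot_scalar_number(n_triplets, "n_triplets", lower = 0)
  stopifnot_scalar_number(triplet_corr_strength, "triplet_corr_strength",
                          lower = 1e-8, upper = 1)
  stopifnot_scalar_number(decoy_factor, "decoy_factor", lower = 0)
  stopifnot_scalar_number(n_gene_sets, "n_gene_sets", lower = 0)
  stopifnot_scalar_number(seed, "seed")
  if (length(groups) < 2L || anyDuplicated(groups)) {
    stop("`groups` must be >= 2 distinct labels", call. = FALSE)
  }
  if (n_hubs > 0 && hub_size >= n_mrna) stop("hub too large", call. = FALSE)
  if (n_triplets + 2 * n_hubs * hub_size > n_mrna) {
    stop("hub too large: planted structures need more mRNAs than n_mrna",
         call. = FALSE)
  }
  if (n_triplets + n_hubs > n_lncrna || n_triplets + n_hubs > n_mirna) {
    stop("not enough lncRNA/miRNA features for the planted structures",
         call. = FALSE)
  }

  structure(list(
    n_mrna = as.integer(n_mrna), n_mirna = as.integer(n_mirna),
    n_lncrna = as.integer(n_lncrna), n_reps = as.integer(n_reps),
    groups = as.character(groups),
    rvm_a = rvm_a, rvm_b = rvm_b,
    de_fraction = de_fraction, effect_log2fc = effect_log2fc,
    n_hubs = as.integer(n_hubs), hub_size = as.integer(hub_size),
    n_triplets = as.integer(n_triplets),
    triplet_corr_strength = triplet_corr_strength,
    decoy_factor = decoy_factor,
    n_gene_sets = as.integer(n_gene_sets),
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Generate a synthetic multi-omic dataset with ground truth
#'
#' Draws mRNA, miRNA and lncRNA expression matrices under the model described
#' in [sim_config()], plants differential features, co-expression hubs and
#' ceRNA triplets, and returns the recovery oracle alongside a miRNA target
#' map (planted pairs plus uncorrelated decoys) and a random gene-set
#' annotation over the mRNA universe.
#'
#' @param config A [sim_config()].
#'
#' @return A list of class `sim_dataset` with elements `mrna`, `mirna`,
#'   `lncrna` ([expression_matrix()]s), `design`, `targets`
#'   ([target_map()]), `genesets` ([gene_set_collection()]), and `truth`
#'   (planted DE features with directions, hub memberships, triplets).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)

  groups <- config$groups
  de_group <- groups[length(groups)]
  n_reps <- config$n_reps
  sample_ids <- as.vector(vapply(groups, function(g) {
    sprintf("%s_%02d", g, seq_len(n_reps))
  }, character(n_reps)))
  design <- group_design(sample_ids, rep(groups, each = n_reps), groups)
  S <- length(sample_ids)
  in_de_group <- as.numeric(unname(design$group_of) == de_group)

  ids <- list(
    mRNA = sprintf("mRNA_%05d", seq_len(config$n_mrna)),
    miRNA = sprintf("miR_%04d", seq_len(config$n_mirna)),
    lncRNA = sprintf("lnc_%04d", seq_len(config$n_lncrna))
  )

  # background: mean + inverse-gamma-variance gaussian noise, log2 scale
  draw_background <- function(n) {
    mu <- stats::rnorm(n, mean = 6, sd = 2)
    tau <- stats::rgamma(n, shape = config$rvm_a, scale = config$rvm_b)
    sigma <- 1 / sqrt(tau)
    x <- matrix(stats::rnorm(n * S), nrow = n) * sigma + mu
    list(x = x, mu = mu)
  }
  bg <- lapply(stats::setNames(nm = names(ids)), function(sp) {
    b <- draw_background(length(ids[[sp]]))
    rownames(b$x) <- ids[[sp]]
    b
  })
  X <- lapply(bg, `[[`, "x")
  MU <- lapply(bg, function(b) stats::setNames(b$mu, rownames(b$x)))
  for (sp in names(X)) colnames(X[[sp]]) <- sample_ids

  eff <- ifelse(config$de_fraction > 0, config$effect_log2fc, 0)
  names(eff) <- names(config$effect_log2fc)

  # --- allocate disjoint planted feature pools -------------------------------
  nt <- config$n_triplets
  nh <- config$n_hubs
  hs <- config$hub_size
  trip_mir <- if (nt > 0) sample(ids$miRNA, nt) else character(0)
  trip_lnc <- if (nt > 0) sample(ids$lncRNA, nt) else character(0)
  trip_mrna <- if (nt > 0) sample(ids$mRNA, nt) else character(0)
  hub_lnc <- if (nh > 0) sample(setdiff(ids$lncRNA, trip_lnc), nh) else character(0)
  hub_mir <- if (nh > 0) sample(setdiff(ids$miRNA, trip_mir), nh) else character(0)
  partner_pool <- setdiff(ids$mRNA, trip_mrna)
  hub_partners <- list()
  if (nh > 0 && hs > 0) {
    picked <- sample(partner_pool, 2 * nh * hs)
    for (i in seq_len(2 * nh)) {
      hub_partners[[i]] <- picked[((i - 1) * hs + 1):(i * hs)]
    }
  }

  # Planted structures share one latent signal z + d*delta*g per structure
  # (g = contrast-group indicator); every member loads the SAME signal (up to
  # sign), so all pooled pairwise correlations equal the calibration target
  # rho after noise scaling: Var(signal) = 1 + delta^2 * pq with
  # pq = Var(g), and noise variance = Var(signal) * (1 - rho) / rho.
  # The common shift magnitude delta is the largest involved species effect:
  # members of a strong-miRNA triplet move together at the miRNA's scale, and
  # each member clears its own (smaller) species fold-change threshold.
  pq <- mean(in_de_group) * (1 - mean(in_de_group))
  struct_noise_sd <- function(delta, rho) sqrt((1 + delta^2 * pq) * (1 - rho) / rho)

  # --- plant ceRNA triplets --------------------------------------------------
  rho <- config$triplet_corr_strength
  trip_delta <- if (all(config$de_fraction > 0)) max(eff) else 0
  trip_noise_sd <- struct_noise_sd(trip_delta, rho)
  trip_dir <- integer(0)
  if (nt > 0) {
    trip_dir <- sample(c(-1L, 1L), nt, replace = TRUE)
    for (t in seq_len(nt)) {
      signal <- stats::rnorm(S) + trip_dir[t] * trip_delta * in_de_group
      plant <- function(id, sp, orient) {
        X[[sp]][id, ] <<- MU[[sp]][id] + orient * signal +
          stats::rnorm(S, sd = trip_noise_sd)
      }
      plant(trip_lnc[t], "lncRNA", +1)
      plant(trip_mrna[t], "mRNA", +1)
      plant(trip_mir[t], "miRNA", -1)
    }
  }

  # --- plant co-expression hubs ---------------------------------------------
  hub_members <- list()
  hub_dir <- integer(0)
  if (nh > 0 && hs > 0) {
    hub_ids <- c(hub_lnc, hub_mir)
    hub_sp <- rep(c("lncRNA", "miRNA"), each = nh)
    hub_dir <- sample(c(-1L, 1L), length(hub_ids), replace = TRUE)
    for (i in seq_along(hub_ids)) {
      sp <- hub_sp[i]
      delta <- if (config$de_fraction[[sp]] > 0 && config$de_fraction[["mRNA"]] > 0)
        max(eff[[sp]], eff[["mRNA"]]) else 0
      hub_noise_sd <- struct_noise_sd(delta, HUB_CORR)
      signal <- stats::rnorm(S) + hub_dir[i] * delta * in_de_group
      orient <- if (sp == "miRNA") -1 else +1   # miRNAs repress their partners
      X[[sp]][hub_ids[i], ] <- MU[[sp]][hub_ids[i]] + orient * signal +
        stats::rnorm(S, sd = hub_noise_sd)
      for (p in hub_partners[[i]]) {
        X$mRNA[p, ] <- MU$mRNA[p] + signal + stats::rnorm(S, sd = hub_noise_sd)
      }
      hub_members[[hub_ids[i]]] <- sort_ids(hub_partners[[i]])
    }
  }

  # --- differential features -------------------------------------------------
  structured <- list(
    mRNA = c(trip_mrna, unlist(hub_partners, use.names = FALSE)),
    miRNA = c(trip_mir, hub_mir),
    lncRNA = c(trip_lnc, hub_lnc)
  )
  de_features <- list()
  de_direction <- list()
  for (sp in names(ids)) {
    frac <- config$de_fraction[[sp]]
    if (frac == 0) {
      de_features[[sp]] <- character(0)
      de_direction[[sp]] <- stats::setNames(integer(0), character(0))
      next
    }
    n_de <- round(frac * length(ids[[sp]]))
    struct_dirs <- stats::setNames(integer(0), character(0))
    if (nt > 0 && trip_delta > 0) {
      tdir <- stats::setNames(
        switch(sp, mRNA = trip_dir, lncRNA = trip_dir, miRNA = -trip_dir),
        switch(sp, mRNA = trip_mrna, lncRNA = trip_lnc, miRNA = trip_mir))
      struct_dirs <- c(struct_dirs, tdir)
    }
    if (nh > 0 && hs > 0 && config$de_fraction[["mRNA"]] > 0) {
      lnc_planted <- config$de_fraction[["lncRNA"]] > 0
      mir_planted <- config$de_fraction[["miRNA"]] > 0
      if (sp == "lncRNA" && lnc_planted) {
        struct_dirs <- c(struct_dirs, stats::setNames(hub_dir[seq_len(nh)], hub_lnc))
      } else if (sp == "miRNA" && mir_planted) {
        struct_dirs <- c(struct_dirs, stats::setNames(-hub_dir[nh + seq_len(nh)], hub_mir))
      } else if (sp == "mRNA") {
        for (i in seq_len(2 * nh)) {
          planted_i <- if (i <= nh) lnc_planted else mir_planted
          if (planted_i) {
            struct_dirs <- c(struct_dirs,
                             stats::setNames(rep(hub_dir[i], hs), hub_partners[[i]]))
          }
        }
      }
    }
    n_extra <- max(0L, n_de - length(struct_dirs))
    pool <- setdiff(ids[[sp]], structured[[sp]])
    extra <- if (n_extra > 0) sample(pool, min(n_extra, length(pool))) else character(0)
    if (length(extra) > 0) {
      dirs <- sample(c(-1L, 1L), length(extra), replace = TRUE)
      X[[sp]][extra, ] <- X[[sp]][extra, , drop = FALSE] +
        outer(dirs * eff[[sp]], in_de_group)
      struct_dirs <- c(struct_dirs, stats::setNames(dirs, extra))
    }
    ord <- order_ids(names(struct_dirs))
    de_direction[[sp]] <- struct_dirs[ord]
    de_features[[sp]] <- names(struct_dirs)[ord]
  }

  # --- target map: planted pairs + uncorrelated decoys -----------------------
  planted_mm <- if (nt > 0) data.frame(mirna = trip_mir, target = trip_mrna,
                                       stringsAsFactors = FALSE) else NULL
  planted_ml <- if (nt > 0) data.frame(mirna = trip_mir, target = trip_lnc,
                                       stringsAsFactors = FALSE) else NULL
  # decoys are drawn among features with no planted structure and no
  # differential effect, so a decoy pair carries no correlation signal at all
  null_mrna <- setdiff(ids$mRNA, union(structured$mRNA, de_features$mRNA))
  null_lncrna <- setdiff(ids$lncRNA, union(structured$lncRNA, de_features$lncRNA))
  sample_decoys <- function(planted, target_ids, n_decoy) {
    if (n_decoy == 0) return(NULL)
    out <- matrix(character(0), ncol = 2)
    planted_key <- if (is.null(planted)) character(0) else
      paste(planted$mirna, planted$target)
    got <- character(0)
    while (length(got) < n_decoy) {
      m <- sample(ids$miRNA, n_decoy, replace = TRUE)
      g <- sample(target_ids, n_decoy, replace = TRUE)
      key <- paste(m, g)
      ok <- !(key %in% planted_key) & !(key %in% got) & !duplicated(key)
      got <- c(got, key[ok])
    }
    got <- got[seq_len(n_decoy)]
    parts <- strsplit(got, " ", fixed = TRUE)
    data.frame(mirna = vapply(parts, `[[`, "", 1),
               target = vapply(parts, `[[`, "", 2),
               stringsAsFactors = FALSE)
  }
  n_decoy <- as.integer(config$decoy_factor * nt)
  mm <- rbind(planted_mm, sample_decoys(planted_mm, null_mrna, n_decoy))
  ml <- rbind(planted_ml, sample_decoys(planted_ml, null_lncrna, n_decoy))
  to_list <- function(df) {
    if (is.null(df) || nrow(df) == 0) return(list())
    split(df$target, df$mirna)
  }
  targets <- target_map(mirna_to_mrna = to_list(mm), mirna_to_lncrna = to_list(ml))

  # --- gene-set annotation over the mRNA universe ----------------------------
  sets <- list()
  if (config$n_gene_sets > 0) {
    for (i in seq_len(config$n_gene_sets)) {
      size <- sample(15:40, 1)
      sets[[sprintf("path_%03d", i)]] <- sample(ids$mRNA, min(size, length(ids$mRNA)))
    }
    # one set enriched in differential mRNAs, so the ORA stage has signal
    if (length(de_features$mRNA) >= 10) {
      sets[["path_de_enriched"]] <-
        sample(de_features$mRNA, min(30, length(de_features$mRNA)))
    }
  }
  genesets <- gene_set_collection(sets, universe = ids$mRNA)

  truth <- list(
    de_features = de_features,
    de_direction = de_direction,
    hub_members = hub_members,
    planted_triplets = if (nt > 0) {
      data.frame(lncrna = trip_lnc, mirna = trip_mir, mrna = trip_mrna,
                 direction = trip_dir, stringsAsFactors = FALSE)
    } else {
      data.frame(lncrna = character(0), mirna = character(0),
                 mrna = character(0), direction = integer(0))
    }
  )

  structure(list(
    mrna = expression_matrix(2^X$mRNA, "mRNA", design),
    mirna = expression_matrix(2^X$miRNA, "miRNA", design),
    lncrna = expression_matrix(2^X$lncRNA, "lncRNA", design),
    design = design,
    targets = targets,
    genesets = genesets,
    truth = truth,
    config = config
  ), class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf(paste0("sim_dataset: %d mRNA, %d miRNA, %d lncRNA x %d samples; ",
                     "%d planted triplets, %d hubs\n"),
              nrow(x$mrna$values), nrow(x$mirna$values), nrow(x$lncrna$values),
              ncol(x$mrna$values), nrow(x$truth$planted_triplets),
              length(x$truth$hub_members)))
  invisible(x)
}
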