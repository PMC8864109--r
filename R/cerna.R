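# Competing-endogenous-RNA (ceRNA) triplet inference: a lncRNA and an mRNA
# that share a targeting miRNA, are both negatively co-expressed with that
# miRNA, and are positively co-expressed with each other, form a sponge
# triplet. Triplets assemble into the ceRNA network whose hubs are ranked
# by degree.

#' Find ceRNA triplets
#'
#' Emits `(lncRNA, miRNA, mRNA)` iff the mRNA and the lncRNA are both
#' targets of the miRNA in the target map, `r(lncRNA, miRNA) <= -neg_cutoff`,
#' `r(mRNA, miRNA) <= -neg_cutoff`, and `r(lncRNA, mRNA) >= +pos_cutoff`
#' (Pearson, log2 scale, across all shared samples). With
#' `de_only = TRUE` candidates are restricted to the supplied differential
#' features of each species.
#'
#' @param targets A [target_map()].
#' @param lnc_mat,mir_mat,mrna_mat [expression_matrix()]s sharing samples.
#' @param neg_cutoff Magnitude of the required anti-correlation with the
#'   miRNA, in (0, 1] (default 0.7).
#' @param pos_cutoff Required lncRNA-mRNA positive correlation, in (0, 1]
#'   (default 0.7).
#' @param de_only Restrict candidates to differential features.
#' @param de_features When `de_only`, a list with character elements
#'   `lncRNA`, `miRNA`, `mRNA`.
#' @return data.frame of class `cerna_triplets`: lncrna_id, mirna_id,
#'   mrna_id, r_lnc_mir, r_mrna_mir, r_lnc_mrna, ordered by
#'   (lncrna, mirna, mrna) id.
#' @export
find_triplets <- function(targets, lnc_mat, mir_mat, mrna_mat,
                          neg_cutoff = 0.7, pos_cutoff = 0.7,
                          de_only = TRUE, de_features = NULL) {
  stopifnot(inherits(targets, "target_map"))
  stopifnot_scalar_number(neg_cutoff, "neg_cutoff", lower = 1e-12, upper = 1)
  stopifnot_scalar_number(pos_cutoff, "pos_cutoff", lower = 1e-12, upper = 1)
  empty <- data.frame(lncrna_id = character(0), mirna_id = character(0),
                      mrna_id = character(0), r_lnc_mir = numeric(0),
                      r_mrna_mir = numeric(0), r_lnc_mrna = numeric(0),
                      stringsAsFactors = FALSE)
  class(empty) <- c("cerna_triplets", class(empty))
  mirnas <- intersect(names(targets$mirna_to_mrna),
                      names(targets$mirna_to_lncrna))
  mirnas <- intersect(mirnas, rownames(mir_mat$values))
  if (de_only) {
    if (is.null(de_features)) {
      stop("`de_features` required when de_only = TRUE", call. = FALSE)
    }
    mirnas <- intersect(mirnas, de_features$miRNA)
  }
  if (length(mirnas) == 0) return(empty)

  shared <- Reduce(intersect, list(colnames(lnc_mat$values),
                                   colnames(mir_mat$values),
                                   colnames(mrna_mat$values)))
  if (length(shared) < 3) stop("< 3 shared samples", call. = FALSE)
  lx <- t(log2_safe(lnc_mat$values[, shared, drop = FALSE]))
  mx <- t(log2_safe(mir_mat$values[, shared, drop = FALSE]))
  gx <- t(log2_safe(mrna_mat$values[, shared, drop = FALSE]))

  restrict <- function(cands, mat_cols, de_set) {
    cands <- intersect(cands, colnames(mat_cols))
    if (de_only) cands <- intersect(cands, de_set)
    sort_ids(cands)
  }
  rows <- list()
  for (m in sort_ids(mirnas)) {
    ls <- restrict(targets$mirna_to_lncrna[[m]], lx, de_features$lncRNA)
    gs <- restrict(targets$mirna_to_mrna[[m]], gx, de_features$mRNA)
    if (length(ls) == 0 || length(gs) == 0) next
    if (stats::sd(mx[, m]) == 0) next
    r_lm <- drop(suppressWarnings(stats::cor(lx[, ls, drop = FALSE], mx[, m])))
    r_gm <- drop(suppressWarnings(stats::cor(gx[, gs, drop = FALSE], mx[, m])))
    ls_ok <- ls[!is.na(r_lm) & r_lm <= -neg_cutoff]
    gs_ok <- gs[!is.na(r_gm) & r_gm <= -neg_cutoff]
    if (length(ls_ok) == 0 || length(gs_ok) == 0) next
    r_lg <- suppressWarnings(stats::cor(lx[, ls_ok, drop = FALSE], gx[, gs_ok, drop = FALSE]))
    for (l in ls_ok) for (g in gs_ok) {
      if (!is.na(r_lg[l, g]) && r_lg[l, g] >= pos_cutoff) {
        rows[[length(rows) + 1L]] <- data.frame(
          lncrna_id = l, mirna_id = m, mrna_id = g,
          r_lnc_mir = unname(r_lm[ls == l]),
          r_mrna_mir = unname(r_gm[gs == g]),
          r_lnc_mrna = r_lg[l, g], stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order_ids(out$lncrna_id, out$mirna_id, out$mrna_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cerna_triplets", class(out))
  out
}

#' Assemble the ceRNA network from triplets
#'
#' Nodes are the union of triplet members (tagged lncRNA/miRNA/mRNA); edges
#' are the deduplicated lncRNA-miRNA and miRNA-mRNA pairs occurring in the
#' triplets; degree is the incident-edge count.
#'
#' @param triplets data.frame from [find_triplets()].
#' @return `rna_network` with an extra field `class_counts`.
#' @export
build_cerna_network <- function(triplets) {
  if (nrow(triplets) == 0) {
    net <- structure(list(nodes = stats::setNames(character(0), character(0)),
                          edges = empty_edges(),
                          degree = stats::setNames(integer(0), character(0))),
                     class = "rna_network")
    net$class_counts <- c(lncRNA = 0L, miRNA = 0L, mRNA = 0L)
    return(net)
  }
  lm <- unique(data.frame(source_id = triplets$lncrna_id,
                          source_class = "lncRNA",
                          target_id = triplets$mirna_id,
                          target_class = "miRNA",
                          r = NA_real_, p_r = NA_real_,
                          stringsAsFactors = FALSE))
  mg <- unique(data.frame(source_id = triplets$mirna_id,
                          source_class = "miRNA",
                          target_id = triplets$mrna_id,
                          target_class = "mRNA",
                          r = NA_real_, p_r = NA_real_,
                          stringsAsFactors = FALSE))
  edges <- rbind(lm, mg)
  edges <- edges[order_ids(edges$source_id, edges$target_id), , drop = FALSE]
  rownames(edges) <- NULL
  nd <- nodes_and_degree(edges)
  nodes <- nd$nodes
  net <- structure(list(nodes = nodes, edges = edges, degree = nd$degree),
                   class = "rna_network")
  net$class_counts <- c(
    lncRNA = sum(unname(nodes) == "lncRNA"),
    miRNA = sum(unname(nodes) == "miRNA"),
    mRNA = sum(unname(nodes) == "mRNA")
  )
  net
}

#' Rank ceRNA hubs per node class
#'
#' Within each class, nodes are sorted by degree descending (ties by id
#' ascending); the top node of each class is flagged as that class's hub.
#'
#' @param net `rna_network` from [build_cerna_network()].
#' @return data.frame: id, class, degree, is_hub.
#' @export
rank_cerna_hubs <- function(net) {
  stopifnot(inherits(net, "rna_network"))
  if (length(net$nodes) == 0) {
    return(data.frame(id = character(0), class = character(0),
                      degree = integer(0), is_hub = logical(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, lapply(c("lncRNA", "miRNA", "mRNA"), function(cl) {
    ranked <- select_hubs(net, cl, min_degree = 0)
    if (nrow(ranked) == 0) return(NULL)
    ranked$is_hub <- seq_len(nrow(ranked)) == 1L
    ranked
  }))
  rownames(out) <- NULL
  out
}
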