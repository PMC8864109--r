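# Pearson co-expression networks across RNA species, degree computation,
# hub selection, and the regulator-to-pathway projection network.

#' Pairwise Pearson correlation between two expression matrices
#'
#' Computes Pearson r on log2 abundances (zeros floored at 2^-20; set
#' `log_scale = FALSE` for raw linear values) for every cross-species feature pair, across the samples
#' shared by the two matrices, together with the two-sided correlation-test
#' p-value (t transform on n - 2 df, as in `cor.test`). Constant features
#' are excluded with a warning.
#'
#' @param mat_a,mat_b [expression_matrix()]s sharing >= 3 samples.
#' @param features_a,features_b Optional feature restrictions (e.g. the
#'   differential features of each species).
#' @param log_scale Correlate log2(x+1) values (default) or raw values.
#' @return data.frame of class `corr_edges`: source_id, source_class,
#'   target_id, target_class, r, p_r (source from `mat_a`).
#' @export
correlate <- function(mat_a, mat_b, features_a = NULL, features_b = NULL,
                      log_scale = TRUE) {
  stopifnot(inherits(mat_a, "expr_matrix"), inherits(mat_b, "expr_matrix"))
  shared <- intersect(colnames(mat_a$values), colnames(mat_b$values))
  if (length(shared) < 3) stop("< 3 shared samples", call. = FALSE)
  pick <- function(mat, feats) {
    feats <- feats %||% rownames(mat$values)
    missing <- setdiff(feats, rownames(mat$values))
    if (length(missing)) {
      stop("unknown features: ", paste(missing, collapse = ", "), call. = FALSE)
    }
    x <- mat$values[sort_ids(unique(feats)), shared, drop = FALSE]
    if (log_scale) x <- log2_safe(x)
    keep <- apply(x, 1, stats::sd) > 0
    if (any(!keep)) {
      warning("excluding constant feature(s): ",
              paste(rownames(x)[!keep], collapse = ", "))
    }
    x[keep, , drop = FALSE]
  }
  xa <- pick(mat_a, features_a)
  xb <- pick(mat_b, features_b)
  if (nrow(xa) == 0 || nrow(xb) == 0) {
    return(empty_edges())
  }
  r <- stats::cor(t(xa), t(xb))
  nS <- length(shared)
  rc <- pmin(pmax(r, -1), 1)
  tt <- rc * sqrt((nS - 2) / pmax(1 - rc^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = nS - 2)
  p[abs(rc) >= 1 - 1e-15] <- 0
  out <- data.frame(
    source_id = rep(rownames(r), times = ncol(r)),
    source_class = mat_a$species,
    target_id = rep(colnames(r), each = nrow(r)),
    target_class = mat_b$species,
    r = as.vector(r),
    p_r = as.vector(p),
    stringsAsFactors = FALSE
  )
  out <- out[order_ids(out$source_id, out$target_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("corr_edges", class(out))
  out
}

# nodes (id -> class) and degrees from an edge list; safe for zero edges
nodes_and_degree <- function(edges) {
  ids <- c(edges$source_id, edges$target_id)
  cls <- c(edges$source_class, edges$target_class)
  if (length(ids) == 0) {
    return(list(nodes = stats::setNames(character(0), character(0)),
                degree = stats::setNames(integer(0), character(0))))
  }
  nodes <- stats::setNames(cls, ids)
  nodes <- nodes[!duplicated(names(nodes))]
  nodes <- nodes[order_ids(names(nodes))]
  degree <- table(factor(ids, levels = names(nodes)))
  list(nodes = nodes, degree = stats::setNames(as.integer(degree), names(nodes)))
}

empty_edges <- function() {
  out <- data.frame(source_id = character(0), source_class = character(0),
                    target_id = character(0), target_class = character(0),
                    r = numeric(0), p_r = numeric(0), stringsAsFactors = FALSE)
  class(out) <- c("corr_edges", class(out))
  out
}

#' Build a co-expression network at a correlation cutoff
#'
#' Keeps edges with `|r| >= r_cutoff` (both signs retained; the sign travels
#' with the edge). Nodes are the endpoints of surviving edges, and a node's
#' degree is its incident-edge count — for a bipartite lncRNA-mRNA network
#' this is exactly "the number of mRNAs regulated by that lncRNA" and vice
#' versa.
#'
#' @param edges data.frame from [correlate()].
#' @param r_cutoff Magnitude cutoff in (0, 1], default 0.99.
#' @return Object of class `rna_network`: `nodes` (named character,
#'   id -> class), `edges` (surviving rows), `degree` (named integer).
#' @export
build_network <- function(edges, r_cutoff = 0.99) {
  stopifnot_scalar_number(r_cutoff, "r_cutoff", lower = 1e-12, upper = 1)
  keep <- edges[abs(edges$r) >= r_cutoff, , drop = FALSE]
  keep <- keep[keep$source_id != keep$target_id |
                 keep$source_class != keep$target_class, , drop = FALSE]
  key <- paste(pmin(keep$source_id, keep$target_id),
               pmax(keep$source_id, keep$target_id))
  keep <- keep[!duplicated(key), , drop = FALSE]
  rownames(keep) <- NULL
  nd <- nodes_and_degree(keep)
  structure(list(nodes = nd$nodes, edges = keep, degree = nd$degree),
            class = "rna_network")
}

#' @export
print.rna_network <- function(x, ...) {
  cls <- table(unname(x$nodes))
  cat(sprintf("rna_network: %d nodes (%s), %d edges\n",
              length(x$nodes),
              paste(sprintf("%s=%d", names(cls), cls), collapse = ", "),
              nrow(x$edges)))
  invisible(x)
}

#' Select hub nodes by degree
#'
#' Nodes of the requested class with degree strictly above `min_degree`,
#' ranked by degree descending with ties broken by id ascending, truncated
#' to `top_k`.
#'
#' @param net An `rna_network`.
#' @param node_class Node class to rank (e.g. `"lncRNA"`).
#' @param min_degree Strict lower bound on degree (default 0 keeps all).
#' @param top_k Maximum number of hubs returned (default all).
#' @return data.frame with columns id, class, degree.
#' @export
select_hubs <- function(net, node_class, min_degree = 0, top_k = Inf) {
  stopifnot(inherits(net, "rna_network"))
  ids <- names(net$nodes)[unname(net$nodes) == node_class]
  deg <- net$degree[ids]
  ids <- ids[deg > min_degree]
  deg <- net$degree[ids]
  ord <- order_ids(-deg, ids)
  ids <- ids[ord][seq_len(min(top_k, length(ids)))]
  data.frame(id = ids, class = rep(node_class, length(ids)),
             degree = as.integer(unname(net$degree[ids])),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Project regulators onto significant pathways
#'
#' Builds the bipartite regulator-to-pathway network: a regulator (lncRNA or
#' miRNA node of the co-expression network) is linked to a significant term
#' iff at least one of its network-correlated mRNAs belongs to that term's
#' member set. The degree of a regulator is the number of pathways it
#' regulates; the degree of a pathway is the number of regulators linked to
#' it.
#'
#' @param net `rna_network` whose edges connect regulators to mRNAs.
#' @param sig_terms data.frame from [significant_terms()].
#' @param annotation The [gene_set_collection()] the terms came from.
#' @return `rna_network` with node classes from the input plus `"pathway"`,
#'   and edges carrying `interaction = "targets_pathway"`.
#' @export
target_pathway_network <- function(net, sig_terms, annotation) {
  stopifnot(inherits(net, "rna_network"),
            inherits(annotation, "gene_set_collection"))
  regulators <- names(net$nodes)[unname(net$nodes) %in% c("lncRNA", "miRNA")]
  edges <- net$edges
  partner_of <- function(reg) {
    unique(c(edges$target_id[edges$source_id == reg & edges$target_class == "mRNA"],
             edges$source_id[edges$target_id == reg & edges$source_class == "mRNA"]))
  }
  rows <- list()
  for (reg in sort_ids(regulators)) {
    mrnas <- partner_of(reg)
    if (length(mrnas) == 0) next
    for (tid in sig_terms$term_id) {
      if (length(intersect(mrnas, annotation$sets[[tid]])) > 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          source_id = reg, source_class = unname(net$nodes[reg]),
          target_id = tid, target_class = "pathway",
          r = NA_real_, p_r = NA_real_, stringsAsFactors = FALSE)
      }
    }
  }
  edges_out <- if (length(rows)) do.call(rbind, rows) else empty_edges()
  edges_out <- edges_out[order_ids(edges_out$source_id, edges_out$target_id), ,
                         drop = FALSE]
  rownames(edges_out) <- NULL
  nd <- nodes_and_degree(edges_out)
  structure(list(nodes = nd$nodes, edges = edges_out, degree = nd$degree),
            class = "rna_network")
}
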