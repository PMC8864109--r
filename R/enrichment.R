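# Over-representation analysis of differential gene sets against pathway/GO
# style annotation, with two-sided Fisher exact or chi-squared testing and
# Benjamini-Hochberg control. -log10 p ("-LgP") is reported for ranking.

#' Gene-set annotation collection
#'
#' @param sets Named list: term id -> character vector of member gene ids.
#'   Members are restricted to the universe; terms left empty by the
#'   restriction are dropped with a warning.
#' @param universe Character vector of gene ids defining the testable
#'   background.
#' @param descriptions Optional named character vector of term descriptions.
#' @return Object of class `gene_set_collection` with `sets`, `descriptions`,
#'   `universe`.
#' @export
gene_set_collection <- function(sets, universe, descriptions = NULL) {
  universe <- sort_ids(unique(as.character(universe)))
  if (length(universe) == 0) stop("empty universe", call. = FALSE)
  if (length(sets) && (is.null(names(sets)) || any(!nzchar(names(sets))))) {
    stop("all gene sets must be named", call. = FALSE)
  }
  restricted <- lapply(sets, function(m) sort_ids(intersect(unique(m), universe)))
  empty <- names(restricted)[lengths(restricted) == 0]
  if (length(empty)) {
    warning("dropping set(s) empty after restriction to the universe: ",
            paste(empty, collapse = ", "))
    restricted <- restricted[lengths(restricted) > 0]
  }
  desc <- stats::setNames(rep("", length(restricted)), names(restricted))
  if (!is.null(descriptions)) {
    keep <- intersect(names(descriptions), names(desc))
    desc[keep] <- descriptions[keep]
  }
  structure(list(sets = restricted, descriptions = desc, universe = universe),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets over %d universe genes\n",
              length(x$sets), length(x$universe)))
  invisible(x)
}

# two-sided Fisher exact p for the 2x2 table with margins (K, N-K) x (n, N-n)
# and observed overlap k: sum of hypergeometric probabilities of all tables
# at most as probable as the observed one (standard two-sided rule, with the
# conventional 1 + 1e-7 relative tolerance for probability ties).
fisher_two_sided <- function(k, K, n, N) {
  support <- max(0L, n + K - N):min(K, n)
  probs <- stats::dhyper(support, K, N - K, n)
  p_obs <- stats::dhyper(k, K, N - K, n)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

chi2_two_by_two <- function(k, K, n, N) {
  tbl <- matrix(c(k, n - k, K - k, N - K - n + k), nrow = 2)
  if (any(rowSums(tbl) == 0) || any(colSums(tbl) == 0)) return(1)
  suppressWarnings(stats::chisq.test(tbl, correct = TRUE)$p.value)
}

#' Over-representation analysis
#'
#' For each term, builds the 2x2 contingency table of (in DE set) x (in
#' term) over the annotation universe and tests association. `fisher` is the
#' two-sided exact hypergeometric test; `chi2` is Pearson's chi-squared with
#' continuity correction; `auto` uses chi-squared when all expected counts
#' are >= 5 and Fisher otherwise. q-values are BH across terms; results are
#' sorted by p then term id.
#'
#' @param de_genes Character vector of differential gene ids; ids outside the
#'   universe are dropped with a warning.
#' @param annotation A [gene_set_collection()].
#' @param method `"fisher"`, `"chi2"`, or `"auto"`.
#' @return data.frame: term_id, name, k (overlap), K (set size), n (DE
#'   size), N (universe size), p, q, neg_lg_p.
#' @export
enrich <- function(de_genes, annotation, method = c("fisher", "chi2", "auto")) {
  method <- match.arg(method)
  stopifnot(inherits(annotation, "gene_set_collection"))
  de_genes <- unique(as.character(de_genes))
  outside <- setdiff(de_genes, annotation$universe)
  if (length(outside)) {
    warning(length(outside), " DE gene(s) outside the universe dropped")
    de_genes <- intersect(de_genes, annotation$universe)
  }
  N <- length(annotation$universe)
  n <- length(de_genes)
  if (n == 0 || length(annotation$sets) == 0) {
    return(data.frame(term_id = character(0), name = character(0),
                      k = integer(0), K = integer(0), n = integer(0),
                      N = integer(0), p = numeric(0), q = numeric(0),
                      neg_lg_p = numeric(0), stringsAsFactors = FALSE))
  }
  term_ids <- names(annotation$sets)
  res <- lapply(term_ids, function(tid) {
    members <- annotation$sets[[tid]]
    K <- length(members)
    k <- length(intersect(de_genes, members))
    use_chi2 <- method == "chi2" ||
      (method == "auto" &&
         min(outer(c(n, N - n), c(K, N - K)) / N) >= 5)
    p <- if (use_chi2) chi2_two_by_two(k, K, n, N) else fisher_two_sided(k, K, n, N)
    data.frame(term_id = tid, name = unname(annotation$descriptions[tid]),
               k = k, K = K, n = n, N = N, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- bh_fdr(out$p)
  out$neg_lg_p <- -log10(out$p)
  out <- out[order_ids(out$p, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Keep significant enrichment terms
#'
#' @param results data.frame from [enrich()].
#' @param q_max Keep terms with BH q below this (default .05).
#' @return Filtered data.frame, ranking preserved.
#' @export
significant_terms <- function(results, q_max = 0.05) {
  stopifnot_scalar_number(q_max, "q_max", lower = 0, upper = 1)
  out <- results[results$q < q_max, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Target genes of a set of miRNAs
#'
#' miRNAs carry no functional annotation themselves; their enrichment is
#' computed over the union of their target mRNAs from the target map.
#'
#' @param mirnas Character vector of miRNA ids.
#' @param targets A [target_map()].
#' @return Sorted character vector of target mRNA ids.
#' @export
mirna_target_genes <- function(mirnas, targets) {
  stopifnot(inherits(targets, "target_map"))
  hit <- intersect(as.character(mirnas), names(targets$mirna_to_mrna))
  sort_ids(unique(unlist(targets$mirna_to_mrna[hit], use.names = FALSE)))
}
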