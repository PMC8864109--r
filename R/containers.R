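#' Sample-to-group design
#'
#' Describes which experimental group each sample belongs to. The default
#' four-arm design mirrors a sham-operated control, chronic intermittent
#' hypoxia (CIH), myocardial infarction (MI), and the combined MI + CIH
#' exposure.
#'
#' @param sample_ids Character vector of unique sample labels.
#' @param groups Character vector, one group label per sample (recycled
#'   against `sample_ids` positionally).
#' @param group_levels Ordered character vector of group labels; defaults to
#'   the unique groups in order of first appearance.
#'
#' @return An object of class `group_design` with fields `sample_ids`,
#'   `group_of` (named character) and `groups` (ordered levels).
#' @export
group_design <- function(sample_ids, groups, group_levels = unique(groups)) {
  sample_ids <- as.character(sample_ids)
  groups <- as.character(groups)
  if (length(sample_ids) != length(groups)) {
    stop("`sample_ids` and `groups` must have the same length", call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ids in design: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (!all(groups %in% group_levels)) {
    stop("groups contain labels not in `group_levels`", call. = FALSE)
  }
  counts <- table(factor(groups, levels = group_levels))
  if (any(counts < 2L)) {
    stop("every group needs >= 2 samples; offending group(s): ",
         paste(names(counts)[counts < 2L], collapse = ", "), call. = FALSE)
  }
  structure(list(
    sample_ids = sample_ids,
    group_of = stats::setNames(groups, sample_ids),
    groups = as.character(group_levels)
  ), class = "group_design")
}

#' @export
print.group_design <- function(x, ...) {
  cat("group_design:", length(x$sample_ids), "samples,",
      length(x$groups), "groups\n")
  print(table(factor(unname(x$group_of), levels = x$groups)))
  invisible(x)
}

design_samples <- function(design, group) {
  names(design$group_of)[unname(design$group_of) == group]
}

#' Expression matrix with species tag and design
#'
#' A features-by-samples abundance matrix on linear scale (non-negative),
#' tagged with the RNA species it profiles and carrying the sample design.
#'
#' @param values Numeric matrix, features in rows (rownames = feature ids),
#'   samples in columns (colnames = sample ids).
#' @param species One of `"mRNA"`, `"miRNA"`, `"lncRNA"`.
#' @param design A [group_design()] whose samples match `colnames(values)`.
#'
#' @return An object of class `expr_matrix` with fields `values`, `species`,
#'   `design`.
#' @export
expression_matrix <- function(values, species = c("mRNA", "miRNA", "lncRNA"),
                              design) {
  species <- match.arg(species)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` needs feature rownames and sample colnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate feature id: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("`values` must be finite and non-negative", call. = FALSE)
  }
  if (!inherits(design, "group_design")) {
    stop("`design` must be a group_design", call. = FALSE)
  }
  if (!setequal(colnames(values), design$sample_ids) ||
      ncol(values) != length(design$sample_ids)) {
    stop("sample columns do not match the design's sample ids", call. = FALSE)
  }
  # fix column order to the design order for determinism
  values <- values[, design$sample_ids, drop = FALSE]
  structure(list(values = values, species = species, design = design),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix (%s): %d features x %d samples\n",
              x$species, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' miRNA target map
#'
#' Holds precomputed miRNA-to-mRNA and miRNA-to-lncRNA target relationships,
#' the stand-in for sequence-based miRNA response element (MRE) prediction.
#'
#' @param mirna_to_mrna Named list: miRNA id -> character vector of mRNA ids.
#' @param mirna_to_lncrna Named list: miRNA id -> character vector of lncRNA
#'   ids.
#'
#' @return Object of class `target_map`.
#' @export
target_map <- function(mirna_to_mrna = list(), mirna_to_lncrna = list()) {
  clean <- function(lst, what) {
    if (length(lst) == 0L) return(stats::setNames(list(), character(0)))
    if (is.null(names(lst)) || any(!nzchar(names(lst)))) {
      stop("all ", what, " entries must be named by miRNA id", call. = FALSE)
    }
    lapply(lst, function(v) {
      v <- as.character(v)
      if (any(!nzchar(v))) stop("empty target id in ", what, call. = FALSE)
      sort_ids(unique(v))
    })
  }
  structure(list(mirna_to_mrna = clean(mirna_to_mrna, "mirna_to_mrna"),
                 mirna_to_lncrna = clean(mirna_to_lncrna, "mirna_to_lncrna")),
            class = "target_map")
}

#' @export
print.target_map <- function(x, ...) {
  cat(sprintf("target_map: %d miRNA->mRNA pairs, %d miRNA->lncRNA pairs\n",
              sum(lengths(x$mirna_to_mrna)), sum(lengths(x$mirna_to_lncrna))))
  invisible(x)
}
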