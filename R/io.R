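# Readers and writers for the plain-text interchange formats: expression
# matrix TSV (feature rows, sample columns), design TSV, target-map TSV,
# GMT gene sets, SIF edge lists, and the ground-truth JSON. Writers and
# readers round-trip.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  path
}

#' Write an expression matrix as TSV
#'
#' First column `feature_id`, then one column per sample.
#' @param matrix An [expression_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "expr_matrix"))
  df <- data.frame(feature_id = rownames(matrix$values),
                   matrix$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  invisible(write_tsv(df, path))
}

#' Read an expression matrix TSV
#'
#' @param path TSV with `feature_id` first column and sample columns.
#' @param species RNA species tag for the matrix.
#' @param design A [group_design()] covering the sample columns.
#' @return An [expression_matrix()].
#' @export
read_matrix <- function(path, species, design) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "feature_id") {
    stop("matrix file must start with a `feature_id` column: ", path,
         call. = FALSE)
  }
  if (anyDuplicated(df$feature_id)) {
    stop("duplicate feature id: ",
         paste(unique(df$feature_id[duplicated(df$feature_id)]),
               collapse = ", "), call. = FALSE)
  }
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- df$feature_id
  expression_matrix(vals, species, design)
}

#' Write / read a sample design TSV (columns `sample`, `group`)
#' @param design A [group_design()].
#' @param path File path.
#' @return `path` invisibly (writer) or a [group_design()] (reader).
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "group_design"))
  df <- data.frame(sample = design$sample_ids,
                   group = unname(design$group_of[design$sample_ids]),
                   stringsAsFactors = FALSE)
  invisible(write_tsv(df, path))
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample", "group") %in% names(df))) {
    stop("design file needs `sample` and `group` columns: ", path,
         call. = FALSE)
  }
  group_design(df$sample, df$group)
}

#' Write / read a miRNA target map TSV
#'
#' Columns `miRNA`, `target_id`, `target_type` (`mRNA` or `lncRNA`).
#' @param targets A [target_map()].
#' @param path File path.
#' @return `path` invisibly (writer) or a [target_map()] (reader).
#' @export
write_targets <- function(targets, path) {
  stopifnot(inherits(targets, "target_map"))
  flatten <- function(lst, type) {
    if (length(lst) == 0) {
      return(data.frame(miRNA = character(0), target_id = character(0),
                        target_type = character(0), stringsAsFactors = FALSE))
    }
    data.frame(miRNA = rep(names(lst), lengths(lst)),
               target_id = unlist(lst, use.names = FALSE),
               target_type = type, stringsAsFactors = FALSE)
  }
  df <- rbind(flatten(targets$mirna_to_mrna, "mRNA"),
              flatten(targets$mirna_to_lncrna, "lncRNA"))
  df <- df[order_ids(df$miRNA, df$target_type, df$target_id), , drop = FALSE]
  invisible(write_tsv(df, path))
}

#' @rdname write_targets
#' @export
read_targets <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("miRNA", "target_id", "target_type")
  if (!all(need %in% names(df))) {
    stop("targets file needs columns ", paste(need, collapse = ", "), ": ",
         path, call. = FALSE)
  }
  bad <- setdiff(unique(df$target_type), c("mRNA", "lncRNA"))
  if (length(bad)) {
    stop("unknown target_type: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  mm <- df[df$target_type == "mRNA", , drop = FALSE]
  ml <- df[df$target_type == "lncRNA", , drop = FALSE]
  target_map(
    mirna_to_mrna = if (nrow(mm)) split(mm$target_id, mm$miRNA) else list(),
    mirna_to_lncrna = if (nrow(ml)) split(ml$target_id, ml$miRNA) else list()
  )
}

#' Write / read gene sets in GMT format
#'
#' One set per line: set name, description, then member gene ids,
#' tab-separated.
#' @param genesets A [gene_set_collection()].
#' @param path File path.
#' @param universe Universe gene ids for the reader (defaults to the union
#'   of all members).
#' @return `path` invisibly (writer) or a [gene_set_collection()] (reader).
#' @export
write_gmt <- function(genesets, path) {
  stopifnot(inherits(genesets, "gene_set_collection"))
  lines <- vapply(names(genesets$sets), function(nm) {
    desc <- genesets$descriptions[[nm]]
    if (!nzchar(desc)) desc <- "na"
    paste(c(nm, desc, genesets$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3)
  if (length(short)) {
    stop("GMT line ", short[1], " has fewer than 3 fields: ", path,
         call. = FALSE)
  }
  sets <- stats::setNames(lapply(parts, function(p) p[-(1:2)]),
                          vapply(parts, `[[`, "", 1))
  desc <- stats::setNames(vapply(parts, `[[`, "", 2), names(sets))
  desc[desc == "na"] <- ""
  if (is.null(universe)) universe <- unique(unlist(sets, use.names = FALSE))
  gene_set_collection(sets, universe = universe, descriptions = desc)
}

#' Write network edges in SIF format
#'
#' `source <TAB> interaction <TAB> target`; correlation edges are typed
#' `pos_corr`/`neg_corr` by the sign of r, projection edges
#' `targets_pathway`, untyped edges `interacts`.
#'
#' @param net An `rna_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sif <- function(net, path) {
  stopifnot(inherits(net, "rna_network"))
  e <- net$edges
  interaction <- ifelse(e$target_class == "pathway", "targets_pathway",
                        ifelse(is.na(e$r), "interacts",
                               ifelse(e$r >= 0, "pos_corr", "neg_corr")))
  writeLines(paste(e$source_id, interaction, e$target_id, sep = "\t"), path)
  invisible(path)
}

#' Write a network's degree table (columns id, class, degree)
#' @param net An `rna_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_degrees <- function(net, path) {
  df <- data.frame(id = names(net$nodes), class = unname(net$nodes),
                   degree = unname(net$degree), stringsAsFactors = FALSE)
  invisible(write_tsv(df, path))
}

#' Write a simulated dataset (and its ground truth) to a directory
#'
#' Emits `mrna.tsv`, `mirna.tsv`, `lncrna.tsv`, `design.tsv`, `targets.tsv`,
#' `pathways.gmt` and `truth.json`; the TSV/GMT files round-trip through the
#' package readers.
#'
#' @param dataset A [simulate_dataset()] result.
#' @param outdir Output directory (created if needed).
#' @return Named character vector of file paths.
#' @export
write_fixture <- function(dataset, outdir) {
  stopifnot(inherits(dataset, "sim_dataset"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("cannot create ", outdir, call. = FALSE)
  paths <- c(
    mrna = file.path(outdir, "mrna.tsv"),
    mirna = file.path(outdir, "mirna.tsv"),
    lncrna = file.path(outdir, "lncrna.tsv"),
    design = file.path(outdir, "design.tsv"),
    targets = file.path(outdir, "targets.tsv"),
    pathways = file.path(outdir, "pathways.gmt"),
    truth = file.path(outdir, "truth.json")
  )
  write_matrix(dataset$mrna, paths[["mrna"]])
  write_matrix(dataset$mirna, paths[["mirna"]])
  write_matrix(dataset$lncrna, paths[["lncrna"]])
  write_design(dataset$design, paths[["design"]])
  write_targets(dataset$targets, paths[["targets"]])
  write_gmt(dataset$genesets, paths[["pathways"]])
  truth <- dataset$truth
  truth_json <- list(
    de_features = truth$de_features,
    de_direction = lapply(truth$de_direction, as.list),
    hub_members = truth$hub_members,
    planted_triplets = truth$planted_triplets
  )
  jsonlite::write_json(truth_json, paths[["truth"]], auto_unbox = FALSE,
                       digits = NA, dataframe = "columns", pretty = TRUE)
  paths
}

#' Read a fixture's ground-truth JSON
#' @param path `truth.json` written by [write_fixture()].
#' @return list with `de_features`, `de_direction`, `hub_members`,
#'   `planted_triplets` (data.frame).
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$de_features <- lapply(x$de_features, as.character)
  x$hub_members <- lapply(x$hub_members, as.character)
  x$de_direction <- lapply(x$de_direction, function(v) {
    stats::setNames(as.integer(unlist(v)), names(v))
  })
  pt <- x$planted_triplets
  if (is.null(pt) || length(pt) == 0 || NROW(pt) == 0) {
    x$planted_triplets <- data.frame(lncrna = character(0),
                                     mirna = character(0),
                                     mrna = character(0),
                                     direction = integer(0),
                                     stringsAsFactors = FALSE)
  } else {
    x$planted_triplets <- as.data.frame(pt, stringsAsFactors = FALSE)
  }
  x
}
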