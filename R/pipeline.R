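# End-to-end driver: differential expression -> clustering -> enrichment ->
# co-expression networks -> target-pathway projection -> ceRNA triplets.
# Every stage writes plain-text artifacts; identical inputs and
# configuration produce byte-identical outputs.

#' Pipeline configuration
#'
#' Bundles the input file paths and stage parameters. Thresholds default to
#' the species-specific fold-change/p cutoffs of [de_thresholds()], the
#' co-expression cutoff to |r| >= 0.99, the ceRNA correlation cutoffs to
#' 0.7, and the contrast to the last design group versus the first
#' (MI_CIH vs Sham in the default design).
#'
#' @param mrna,mirna,lncrna,design,targets,pathways Input file paths (the
#'   dialects written by [write_fixture()]).
#' @param outdir Output directory.
#' @param contrast Character pair `c(groupA, groupB)`; B is the affected
#'   group. `NULL` picks `c(first, last)` design group.
#' @param normalize_method Passed to [normalize_matrix()]; default `"none"`
#'   because the expected inputs are already-normalized signal intensities
#'   (use `"library_size"` for unnormalized abundances).
#' @param fc_min Named numeric fold-change cutoffs per species; defaults per
#'   [de_thresholds()].
#' @param p_max DE significance cutoff (raw p by default).
#' @param use_q Filter DE on BH q instead of raw p.
#' @param r_cutoff Co-expression network |r| cutoff.
#' @param neg_cutoff,pos_cutoff ceRNA correlation cutoffs.
#' @param de_only Restrict ceRNA candidates to differential features.
#' @param q_max Enrichment significance cutoff (on BH q).
#' @param enrich_method Enrichment test: fisher, chi2 or auto.
#' @param min_hub_degree Strict degree cutoff for co-expression hubs.
#' @param seed Recorded in the run log (the pipeline itself is
#'   deterministic).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(mrna, mirna, lncrna, design, targets, pathways,
                            outdir,
                            contrast = NULL,
                            normalize_method = "none",
                            fc_min = NULL,
                            p_max = 0.05,
                            use_q = FALSE,
                            r_cutoff = 0.99,
                            neg_cutoff = 0.7,
                            pos_cutoff = 0.7,
                            de_only = TRUE,
                            q_max = 0.05,
                            enrich_method = "fisher",
                            min_hub_degree = 80,
                            seed = 1L) {
  fc_default <- c(mRNA = de_thresholds("mRNA")$fc_min,
                  miRNA = de_thresholds("miRNA")$fc_min,
                  lncRNA = de_thresholds("lncRNA")$fc_min)
  if (is.null(fc_min)) fc_min <- fc_default
  if (!all(c("mRNA", "miRNA", "lncRNA") %in% names(fc_min))) {
    stop("fc_min must be named over mRNA/miRNA/lncRNA", call. = FALSE)
  }
  stopifnot_scalar_number(p_max, "p_max", lower = 0, upper = 1)
  stopifnot_scalar_number(r_cutoff, "r_cutoff", lower = 1e-12, upper = 1)
  stopifnot_scalar_number(q_max, "q_max", lower = 0, upper = 1)
  structure(list(
    paths = list(mrna = mrna, mirna = mirna, lncrna = lncrna,
                 design = design, targets = targets, pathways = pathways),
    outdir = outdir, contrast = contrast,
    normalize_method = normalize_method,
    fc_min = fc_min[c("mRNA", "miRNA", "lncRNA")],
    p_max = p_max, use_q = use_q,
    r_cutoff = r_cutoff, neg_cutoff = neg_cutoff, pos_cutoff = pos_cutoff,
    de_only = de_only, q_max = q_max, enrich_method = enrich_method,
    min_hub_degree = min_hub_degree, seed = as.integer(seed)
  ), class = "pipeline_config")
}

pipeline_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full inference pipeline
#'
#' Reads the inputs, then runs: optional normalization; RVM moderated
#' t-tests per species with species-specific fold-change filters;
#' hierarchical clustering of the differential features; over-representation
#' analysis of the differential mRNAs (and of the differential miRNAs
#' through their target genes); lncRNA-mRNA and miRNA-mRNA co-expression
#' networks at the |r| cutoff with hub selection; regulator-to-pathway
#' projection networks; and ceRNA triplet inference with the ceRNA network
#' and its hubs. All artifacts plus a run log are written under
#' `config$outdir`.
#'
#' @param config A [pipeline_config()].
#' @return Named character vector (the output-file manifest), invisibly
#'   returned with attribute `summary` (per-stage counts).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  for (p in unlist(config$paths)) {
    if (!file.exists(p)) stop("input file missing: ", p, call. = FALSE)
  }
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- character(0)
  emit <- function(name, path) manifest[[name]] <<- path
  counts <- list()

  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE)
    })
  }

  # --- load ------------------------------------------------------------------
  design <- run_stage("load", read_design(config$paths$design))
  mats <- run_stage("load", list(
    mRNA = read_matrix(config$paths$mrna, "mRNA", design),
    miRNA = read_matrix(config$paths$mirna, "miRNA", design),
    lncRNA = read_matrix(config$paths$lncrna, "lncRNA", design)
  ))
  targets <- run_stage("load", read_targets(config$paths$targets))
  genesets <- run_stage("load",
                        read_gmt(config$paths$pathways,
                                 universe = rownames(mats$mRNA$values)))
  contrast <- config$contrast %||%
    c(design$groups[1], design$groups[length(design$groups)])
  pipeline_log("load", "%d/%d/%d mRNA/miRNA/lncRNA features, %d samples; contrast %s vs %s",
               nrow(mats$mRNA$values), nrow(mats$miRNA$values),
               nrow(mats$lncRNA$values), length(design$sample_ids),
               contrast[2], contrast[1])

  # --- normalize + differential expression -----------------------------------
  mats <- run_stage("normalize", lapply(mats, normalize_matrix,
                                        method = config$normalize_method))
  de <- list(); de_ids <- list()
  for (sp in names(mats)) {
    res <- run_stage("diffexp", {
      prior <- fit_rvm_prior(mats[[sp]], contrast[1], contrast[2])
      res <- rvm_t_test(mats[[sp]], contrast[1], contrast[2], prior)
      filter_de(res, fc_min = config$fc_min[[sp]], p_max = config$p_max,
                use_q = config$use_q)
    })
    de[[sp]] <- res
    de_ids[[sp]] <- de_feature_ids(res)
    counts[[paste0("de_", sp)]] <- length(de_ids[[sp]])
    f <- file.path(outdir, sprintf("de_%s.tsv", tolower(sp)))
    write_tsv(res, f); emit(paste0("de_", tolower(sp)), f)
    pipeline_log("diffexp", "%s: %d/%d features pass (FC >= %g, p < %g)",
                 sp, length(de_ids[[sp]]), nrow(res),
                 config$fc_min[[sp]], config$p_max)
  }

  # --- hierarchical clustering of DE features --------------------------------
  for (sp in names(mats)) {
    if (length(de_ids[[sp]]) >= 2) {
      cl <- run_stage("cluster",
                      suppressWarnings(cluster_features(mats[[sp]], de_ids[[sp]])))
      f <- file.path(outdir, sprintf("cluster_%s_leaves.txt", tolower(sp)))
      writeLines(cl$order, f); emit(paste0("cluster_", tolower(sp)), f)
    }
  }

  # --- enrichment ------------------------------------------------------------
  enr_mrna <- run_stage("enrich",
                        suppressWarnings(enrich(de_ids$mRNA, genesets,
                                                method = config$enrich_method)))
  sig_mrna <- significant_terms(enr_mrna, config$q_max)
  f <- file.path(outdir, "enrichment_mrna.tsv")
  write_tsv(enr_mrna, f); emit("enrichment_mrna", f)
  mirna_genes <- mirna_target_genes(de_ids$miRNA, targets)
  enr_mirna <- run_stage("enrich",
                         suppressWarnings(enrich(mirna_genes, genesets,
                                                 method = config$enrich_method)))
  sig_mirna <- significant_terms(enr_mirna, config$q_max)
  f <- file.path(outdir, "enrichment_mirna.tsv")
  write_tsv(enr_mirna, f); emit("enrichment_mirna", f)
  counts$sig_terms_mrna <- nrow(sig_mrna)
  counts$sig_terms_mirna <- nrow(sig_mirna)
  pipeline_log("enrich", "%d significant terms (mRNA), %d (miRNA targets) at q < %g",
               nrow(sig_mrna), nrow(sig_mirna), config$q_max)

  # --- co-expression networks ------------------------------------------------
  nets <- list()
  for (reg in c("lncRNA", "miRNA")) {
    edges <- if (length(de_ids[[reg]]) == 0 || length(de_ids$mRNA) == 0) {
      empty_edges()   # the network spans differential features only
    } else {
      run_stage("coexpr", suppressWarnings(
        correlate(mats[[reg]], mats$mRNA,
                  features_a = de_ids[[reg]], features_b = de_ids$mRNA)))
    }
    net <- build_network(edges, r_cutoff = config$r_cutoff)
    nets[[reg]] <- net
    tag <- if (reg == "lncRNA") "lncrna_mrna" else "mirna_mrna"
    f <- file.path(outdir, sprintf("network_%s.sif", tag))
    write_sif(net, f); emit(paste0("network_", tag, "_sif"), f)
    f <- file.path(outdir, sprintf("network_%s_edges.tsv", tag))
    write_tsv(net$edges, f); emit(paste0("network_", tag, "_edges"), f)
    f <- file.path(outdir, sprintf("network_%s_degrees.tsv", tag))
    write_degrees(net, f); emit(paste0("network_", tag, "_degrees"), f)
    hubs <- select_hubs(net, reg, min_degree = config$min_hub_degree)
    f <- file.path(outdir, sprintf("hubs_%s.tsv", tolower(reg)))
    write_tsv(hubs, f); emit(paste0("hubs_", tolower(reg)), f)
    counts[[paste0("edges_", tag)]] <- nrow(net$edges)
    counts[[paste0("hubs_", reg)]] <- nrow(hubs)
    pipeline_log("coexpr", "%s-mRNA: %d edges at |r| >= %g; %d %s hub(s) with degree > %d",
                 reg, nrow(net$edges), config$r_cutoff, nrow(hubs), reg,
                 config$min_hub_degree)

    # --- regulator -> pathway projection ------------------------------------
    sig <- if (reg == "lncRNA") sig_mrna else sig_mirna
    tp <- run_stage("target_pathway", target_pathway_network(net, sig, genesets))
    f <- file.path(outdir, sprintf("pathway_network_%s.sif", tolower(reg)))
    write_sif(tp, f); emit(paste0("pathway_network_", tolower(reg), "_sif"), f)
    f <- file.path(outdir, sprintf("pathway_network_%s_degrees.tsv", tolower(reg)))
    write_degrees(tp, f); emit(paste0("pathway_network_", tolower(reg), "_degrees"), f)
  }

  # --- ceRNA triplets --------------------------------------------------------
  triplets <- run_stage("cerna", find_triplets(
    targets, mats$lncRNA, mats$miRNA, mats$mRNA,
    neg_cutoff = config$neg_cutoff, pos_cutoff = config$pos_cutoff,
    de_only = config$de_only, de_features = de_ids))
  f <- file.path(outdir, "triplets.tsv")
  write_tsv(triplets, f); emit("triplets", f)
  cnet <- build_cerna_network(triplets)
  f <- file.path(outdir, "cerna_network.sif")
  write_sif(cnet, f); emit("cerna_network_sif", f)
  f <- file.path(outdir, "cerna_degrees.tsv")
  write_degrees(cnet, f); emit("cerna_degrees", f)
  hubs <- rank_cerna_hubs(cnet)
  counts$triplets <- nrow(triplets)
  counts$cerna_nodes <- length(cnet$nodes)
  pipeline_log("cerna", "%d triplets; ceRNA network: %d lncRNA, %d miRNA, %d mRNA nodes",
               nrow(triplets), cnet$class_counts[["lncRNA"]],
               cnet$class_counts[["miRNA"]], cnet$class_counts[["mRNA"]])
  summary_json <- list(
    class_counts = as.list(cnet$class_counts),
    hubs = if (is.null(hubs) || nrow(hubs) == 0) list() else
      split(hubs$id[hubs$is_hub], hubs$class[hubs$is_hub]),
    counts = counts
  )
  f <- file.path(outdir, "cerna_summary.json")
  jsonlite::write_json(summary_json, f, auto_unbox = TRUE, pretty = TRUE)
  emit("cerna_summary", f)

  # --- run log: everything needed to reproduce the run -----------------------
  log_lines <- c(
    "cernet run log",
    paste0("package_version: ", as.character(utils::packageVersion("cernet"))),
    paste0("seed: ", config$seed),
    paste0("contrast: ", contrast[2], " vs ", contrast[1]),
    paste0("normalize_method: ", config$normalize_method),
    paste0("fc_min: ", paste(sprintf("%s=%g", names(config$fc_min),
                                     config$fc_min), collapse = " ")),
    paste0("p_max: ", config$p_max, " use_q: ", config$use_q),
    paste0("r_cutoff: ", config$r_cutoff),
    paste0("neg_cutoff: ", config$neg_cutoff, " pos_cutoff: ",
           config$pos_cutoff, " de_only: ", config$de_only),
    paste0("q_max: ", config$q_max, " enrich_method: ", config$enrich_method),
    paste0("min_hub_degree: ", config$min_hub_degree),
    paste0("inputs: ", paste(unlist(config$paths), collapse = " ")),
    paste0("counts: ", paste(sprintf("%s=%d", names(counts),
                                     unlist(counts)), collapse = " "))
  )
  f <- file.path(outdir, "run_log.txt")
  writeLines(log_lines, f)
  emit("run_log", f)

  invisible(structure(manifest, summary = counts))
}
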