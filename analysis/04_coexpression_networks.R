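#!/usr/bin/env Rscript
# Stage 4: lncRNA-mRNA and miRNA-mRNA co-expression networks (|r| >= 0.99
# across all 32 samples, differential features only), degree-based hub
# selection (degree > 80), and projection of the regulators onto the
# significant pathways.

library(cernet)

data_dir <- "results/data"
de_dir <- "results/02_diffexp"
enr_dir <- "results/03_enrichment"
outdir <- "results/04_networks"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

design <- read_design(file.path(data_dir, "design.tsv"))
truth <- read_truth(file.path(data_dir, "truth.json"))
mats <- list(
  mRNA = read_matrix(file.path(data_dir, "mrna.tsv"), "mRNA", design),
  miRNA = read_matrix(file.path(data_dir, "mirna.tsv"), "miRNA", design),
  lncRNA = read_matrix(file.path(data_dir, "lncrna.tsv"), "lncRNA", design)
)
genesets <- read_gmt(file.path(data_dir, "pathways.gmt"),
                     universe = rownames(mats$mRNA$values))
de_ids <- function(sp) {
  de <- utils::read.delim(file.path(de_dir, sprintf("de_%s.tsv", sp)))
  de$feature_id[de$passes]
}

for (reg in c("lncRNA", "miRNA")) {
  tag <- tolower(reg)
  edges <- suppressWarnings(
    correlate(mats[[reg]], mats$mRNA,
              features_a = de_ids(tag), features_b = de_ids("mrna")))
  net <- build_network(edges, r_cutoff = 0.99)
  write_sif(net, file.path(outdir, sprintf("network_%s_mrna.sif", tag)))
  write_degrees(net, file.path(outdir, sprintf("network_%s_mrna_degrees.tsv", tag)))
  hubs <- select_hubs(net, reg, min_degree = 80)
  utils::write.table(hubs, file.path(outdir, sprintf("hubs_%s.tsv", tag)),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  planted <- grep(if (reg == "lncRNA") "^lnc" else "^miR",
                  names(truth$hub_members), value = TRUE)
  message(sprintf(
    "%s-mRNA: %d edges (%d neg); hubs(deg>80): %s | planted: %s | recall %.2f",
    reg, nrow(net$edges), sum(net$edges$r < 0),
    paste(hubs$id, collapse = ","), paste(planted, collapse = ","),
    if (length(planted)) mean(planted %in% hubs$id) else NA))

  # pathway significance: mRNA enrichment for lncRNA regulators, the
  # target-gene-based miRNA enrichment for miRNA regulators
  enr_file <- if (reg == "lncRNA") "enrichment_mrna.tsv" else "enrichment_mirna.tsv"
  sig <- significant_terms(utils::read.delim(file.path(enr_dir, enr_file)), 0.05)
  tp <- target_pathway_network(net, sig, genesets)
  write_sif(tp, file.path(outdir, sprintf("pathway_network_%s.sif", tag)))
  write_degrees(tp, file.path(outdir, sprintf("pathway_network_%s_degrees.tsv", tag)))
  message(sprintf("  -> pathway projection: %d regulators x %d pathways, %d links",
                  sum(unname(tp$nodes) != "pathway"),
                  sum(unname(tp$nodes) == "pathway"), nrow(tp$edges)))
}
message("wrote network SIF/degree tables -> ", outdir)
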