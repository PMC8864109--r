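#!/usr/bin/env Rscript
# Stage 3: over-representation analysis of the differential features.
#
# mRNAs are tested directly against the gene-set annotation; miRNAs carry no
# annotation of their own, so their enrichment runs over the union of their
# target genes from the target map. Two-sided Fisher exact tests with BH
# control; terms ranked by -log10 p.

library(cernet)

data_dir <- "results/data"
de_dir <- "results/02_diffexp"
outdir <- "results/03_enrichment"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

design <- read_design(file.path(data_dir, "design.tsv"))
mrna <- read_matrix(file.path(data_dir, "mrna.tsv"), "mRNA", design)
genesets <- read_gmt(file.path(data_dir, "pathways.gmt"),
                     universe = rownames(mrna$values))
targets <- read_targets(file.path(data_dir, "targets.tsv"))

de_ids <- function(sp) {
  de <- utils::read.delim(file.path(de_dir, sprintf("de_%s.tsv", sp)))
  de$feature_id[de$passes]
}

enr_mrna <- suppressWarnings(enrich(de_ids("mrna"), genesets))
utils::write.table(enr_mrna, file.path(outdir, "enrichment_mrna.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
sig <- significant_terms(enr_mrna, 0.05)
message(sprintf("mRNA: %d/%d terms significant at q < .05; top: %s (-LgP %.1f)",
                nrow(sig), nrow(enr_mrna),
                if (nrow(sig)) sig$term_id[1] else "none",
                if (nrow(sig)) sig$neg_lg_p[1] else NA))

mirna_genes <- mirna_target_genes(de_ids("mirna"), targets)
enr_mirna <- suppressWarnings(enrich(mirna_genes, genesets))
utils::write.table(enr_mirna, file.path(outdir, "enrichment_mirna.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf("miRNA (via %d target genes): %d significant terms",
                length(mirna_genes),
                nrow(significant_terms(enr_mirna, 0.05))))
message("wrote enrichment tables -> ", outdir)
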