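#!/usr/bin/env Rscript
# Stage 1: generate the study-scale synthetic dataset.
#
# Emulates a four-arm cardiac profiling design (Sham, CIH, MI, MI_CIH;
# n = 8/group) at reduced feature scale: 1000 mRNAs, 80 miRNAs, 200 lncRNAs,
# with 10 planted ceRNA triplets, 2 lncRNA hubs and 2 miRNA hubs (100 mRNA
# partners each), and species-scale differential effects.

library(cernet)

outdir <- "results/data"
cfg <- sim_config(seed = 1)
ds <- simulate_dataset(cfg)
paths <- write_fixture(ds, outdir)

message("wrote: ", paste(basename(paths), collapse = ", "), " -> ", outdir)
message(sprintf("planted: %d/%d/%d DE mRNA/miRNA/lncRNA, %d hubs, %d triplets",
                length(ds$truth$de_features$mRNA),
                length(ds$truth$de_features$miRNA),
                length(ds$truth$de_features$lncRNA),
                length(ds$truth$hub_members),
                nrow(ds$truth$planted_triplets)))
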