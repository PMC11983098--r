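#!/usr/bin/env Rscript
# Step 1 — simulate the study-like experiment.
#
# Generates a compact yeast-like genome (5673 genes in RP/RiBi/GR/other
# groups), promoter sequences with PAC/RRPE motifs planted preferentially
# in the growth-regulated groups, and stranded single-end ChIP-seq read
# sets (H3K9ac and Rpb1, vehicle and treated) with a 5% spike-in and
# planted per-gene log2 fold changes (between-track correlation 0.76).
# Tables go to results/sim/; the (large) read files go to scratch/sim/.

suppressMessages(library(promacet))

seed <- 1
cfg <- sim_config(n_genes = 5673, mean_midpoints = 200, seed = seed)

dir.create("results/sim", recursive = TRUE, showWarnings = FALSE)
sim <- write_simulation(cfg, "scratch/sim",
                        tracks = c("H3K9ac", "Rpb1"),
                        conditions = c("vehicle", "treated"))
for (f in c("genes.tsv", "chroms.tsv", "ground_truth.tsv",
            "sim_config.yaml"))
  file.copy(file.path("scratch/sim", f), file.path("results/sim", f),
            overwrite = TRUE)

cat("genes:", nrow(sim$annotation$genes), "on",
    sum(sim$annotation$chroms$species == "target"),
    "target chromosomes + 1 spike-in chromosome\n")
cat("planted repressed genes:", sum(sim$truth$repressed), "\n")
cat("planted fold-change correlation:",
    round(cor(sim$truth$fc_h3k9ac, sim$truth$fc_rpb1), 3), "\n")
cat("read files:", paste(basename(unlist(sim$read_paths)),
                         collapse = ", "), "-> scratch/sim/\n")
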