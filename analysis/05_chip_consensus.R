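#!/usr/bin/env Rscript
# Replicate-consensus ChIP peaks on a toy genome: consensus calling at
# k of n support, genome occupancy, promoter annotation and a gene-level
# binding matrix contrasting two conditions.

suppressPackageStartupMessages(library(drugsynergy))
dir.create("results", showWarnings = FALSE)

genes <- gene_annotation(gene_id = sprintf("G%03d", 1:40),
                         chrom = "chr1", strand = rep(c("+", "-"), 20),
                         tss = seq(12000, by = 25000, length.out = 40),
                         body_start = seq(12000, by = 25000, length.out = 40),
                         body_end = seq(12000, by = 25000, length.out = 40) + 8000)

# vehicle retains binding genome-wide; treatment keeps only a small subset
veh <- gen_peak_replicates(seed = 505, n_peaks = 200, n_rep = 3,
                           jitter = 100, dropout = 0.1)
kept <- data.frame(veh$truth)[sample(seq_len(nrow(veh$truth)), 15), ]
trt <- gen_peak_replicates(seed = 506, n_rep = 3, jitter = 100,
                           dropout = 0.1, plant_at = kept)

cons <- list(vehicle = consensus_peaks(veh$replicates, 2),
             treated = consensus_peaks(trt$replicates, 2))
for (nm in names(cons)) write_bed(cons[[nm]], sprintf("results/05_consensus_%s.bed", nm))

occ <- data.frame(condition = names(cons),
                  n_peaks = vapply(cons, nrow, integer(1)),
                  coverage_bp = vapply(cons, merged_coverage_bp, numeric(1)))
write_tsv(occ, "results/05_occupancy.tsv")

ann <- annotate_peaks(cons$vehicle, genes)
write_tsv(data.frame(category = names(ann$counts), count = ann$counts,
                     fraction = ann$fractions),
          "results/05_vehicle_annotation.tsv")

bm <- gene_binding_matrix(cons, genes)
write_tsv(data.frame(gene_id = rownames(bm$bound), bm$bound),
          "results/05_binding_matrix.tsv")
cat("wrote results/05_consensus_*.bed and results/05_*.tsv\n")
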