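#!/usr/bin/env Rscript
# Build the study panel: two cattle-like breed groups (10 + 9 diploid
# samples) with 20,000 phased SNPs on one 10-Mb chromosome, Balding-Nichols
# drift at FST 0.1, 10 planted breed-1 signature genes, one planted
# heterozygous (opposite-zygosity) gene, and one hard sweep in breed 1.
# Writes VCF / BED / label and truth TSVs under results/fixture/.

library(breedsig)

cfg <- sim_config(seed = 42L)
sim <- simulate_panel(cfg)
paths <- write_fixture(sim$panel, sim$genes, "results/fixture",
                       truth = sim$truth)

cat("Simulated", n_samples(sim$panel), "samples x", n_sites(sim$panel),
    "SNPs;", nrow(sim$genes), "genes\n")
cat("Planted signature genes:",
    paste(sim$truth$signature_gene_ids, collapse = ", "), "\n")
cat("Planted heterozygous gene:", sim$truth$het_gene_ids, "\n")
sw <- sim$truth$sweep_windows[[1]]
cat(sprintf("Planted sweep: %s:%d-%d in %s\n", sw$chrom,
            as.integer(sw$start), as.integer(sw$end), sw$breed))
cat("Wrote:", paste(basename(paths), collapse = ", "),
    "under results/fixture/\n")
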