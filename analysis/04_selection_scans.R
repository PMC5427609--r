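#!/usr/bin/env Rscript
# Cross-population selection scans between the two breeds: XP-EHH over
# 50-kb windows with SNP-count-binned empirical p-values, and the
# simplified XP-CLR-style differentiation scan (600-SNP cap, 0.95
# redundancy down-weighting, top 1%).  Candidate genes are assigned with a
# 25-kb flank and intersected with the wMI gene list.
# Writes results/scans/.

library(breedsig)

labs <- read_breed_labels("results/fixture/labels.tsv")
panel <- recode_major_minor(read_vcf("results/fixture/panel.vcf", labs))
genes <- read_genes("results/fixture/genes.bed")
truth <- read.table("results/fixture/truth.tsv", header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
mi_genes <- readLines("results/genes/genes_mi.txt")

a <- subset_breeds(panel, "breed1")
b <- subset_breeds(panel, "breed2")

scan <- xpehh_scan(a, b)
win <- bin_empirical_p(scan$windows)
sel_win <- win[win$selected, , drop = FALSE]
cat(sprintf("XP-EHH: %d windows, %d selected (positive stat, empirical p < 0.01)\n",
            nrow(win), nrow(sel_win)))
sweep <- truth[truth$feature == "sweep", "detail"]
cat("Planted sweep region:", sweep, "| selected windows:",
    paste(sprintf("%d-%d", sel_win$start, sel_win$end), collapse = ", "),
    "\n")

xpehh_genes <- assign_candidate_genes(sel_win, genes)
clr <- xpclr_lite(ternary_encode(a), ternary_encode(b))
xpclr_genes <- assign_candidate_genes(clr[clr$selected, , drop = FALSE],
                                      genes)
cat(sprintf("Candidate genes: %d (XP-EHH), %d (XP-CLR)\n",
            length(xpehh_genes), length(xpclr_genes)))
cat(sprintf("Intersections with the MI list: %d (MI&XP-EHH), %d (MI&XP-CLR)\n",
            length(intersect_gene_lists(mi_genes, xpehh_genes)),
            length(intersect_gene_lists(mi_genes, xpclr_genes))))

dir.create("results/scans", recursive = TRUE, showWarnings = FALSE)
write.table(scan$sites, "results/scans/xpehh_sites.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(win, "results/scans/xpehh_windows.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(clr, "results/scans/xpclr_windows.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
writeLines(xpehh_genes, "results/scans/genes_xpehh.txt")
writeLines(xpclr_genes, "results/scans/genes_xpclr.txt")
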