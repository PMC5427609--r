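#!/usr/bin/env Rscript
# Contingency-table statistics: per-chromosome Fisher enrichment of the
# MI-selected SNPs, and case-control genotype tests (dominant / recessive
# Fisher, codominant Cochran-Armitage) with Bonferroni correction.
# Writes results/assoc/.

library(breedsig)

labs <- read_breed_labels("results/fixture/labels.tsv")
panel <- recode_major_minor(read_vcf("results/fixture/panel.vcf", labs))
site_mi_tab <- read.table("results/mi/site_mi.tsv", header = TRUE,
                          sep = "\t", stringsAsFactors = FALSE)

enr <- chromosome_enrichment(site_mi_tab$selected, site_mi_tab$chrom)
cat("Per-chromosome enrichment of MI-selected SNPs:\n")
print(enr, row.names = FALSE)

tern <- ternary_encode(panel)
assoc <- do.call(rbind, lapply(c("dominant", "recessive", "codominant"),
                               function(m) case_control_test(tern, model = m)))
for (m in unique(assoc$model)) {
  sub <- assoc[assoc$model == m, ]
  cat(sprintf("%-10s model: %d / %d sites significant after Bonferroni (0.05)\n",
              m, sum(sub$bonferroni_p < 0.05), nrow(sub)))
}

dir.create("results/assoc", recursive = TRUE, showWarnings = FALSE)
write.table(enr, "results/assoc/enrichment.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(assoc, "results/assoc/assoc_tests.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
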