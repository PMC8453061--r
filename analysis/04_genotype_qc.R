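#!/usr/bin/env Rscript
# Stage 4: genotype quality control and genetic principal components.
#
# Applies the array-QC cascade — sample call rate < 95%, SNP call rate
# < 95%, MAF < 1%, Hardy-Weinberg exact p < 1e-6, relatedness
# (PIHAT > 0.2, keeping the higher-call-rate member) — then LD-prunes
# (r^2 > 0.2) and computes the first 5 PCs used for the sensitivity
# models.

suppressMessages(library(mitosurv))
inp <- "results/analysis/inputs"
out <- "results/analysis"

g <- read_vcf_genotypes(file.path(inp, "genotypes.vcf"))
qc <- run_genotype_qc(g)
print(qc)

write_tsv(qc$removed_samples, file.path(out, "qc_removed_samples.tsv"))
write_tsv(qc$removed_snps, file.path(out, "qc_removed_snps.tsv"))
write_tsv(data.frame(sample_id = rownames(qc$pcs), qc$pcs),
          file.path(out, "pc_scores.tsv"))

cat("sample removals:\n"); print(table(qc$removed_samples$reason))
cat("SNP removals:\n"); print(table(qc$removed_snps$reason))
if (nrow(qc$related_pairs)) {
  cat("flagged related pairs:\n")
  print(qc$related_pairs)
}
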