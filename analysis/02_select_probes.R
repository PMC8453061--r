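#!/usr/bin/env Rscript
# Stage 2: mitochondrial probe selection.
#
# Screens every array probe for a 100%-identity match to the circular
# mitochondrial reference and for its minimum Hamming distance to any
# nuclear window on either strand (the NUMT guard), keeping probes with
# an exact mito hit and nuclear distance >= 2.

suppressMessages(library(mitosurv))
inp <- "results/analysis/inputs"
out <- "results/analysis"

refs_all <- read_fasta(file.path(inp, "references.fasta"))
refs <- reference_set(mito = refs_all[["mito"]], nuclear = refs_all[-1])
probes_fa <- read_fasta(file.path(inp, "probes.fasta"))
probes <- data.frame(probe_id = names(probes_fa), sequence = probes_fa,
                     row.names = NULL)

sel <- select_mtdna_probes(probes, refs, min_mm = 2)
write_tsv(sel$report, file.path(out, "probe_selection.tsv"))

cat(sprintf("%d of %d probes selected\n", nrow(sel$selected), nrow(probes)))
cat("exclusion reasons:\n")
print(table(sel$report$reason[!sel$report$selected]))
cat(sprintf("nuclear mismatch of selected probes: %d-%d\n",
            min(sel$selected$min_nuclear_mismatch),
            max(sel$selected$min_nuclear_mismatch)))
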