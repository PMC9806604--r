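#!/usr/bin/env Rscript

# Stage 2 -- map and count every sample of the simulated cohort.
#
# Runs the internal exact mapper (every simulated read is an exact genome
# substring, so mapping is total and uniqueness is exact), then counts the
# reads of the four diagnostic motif classes -- (CCCTAAA)5, (TTTAGGG)5,
# Cen1, Cen2 -- among the mapping reads of every sample. One TSV row per
# sample, including the RMUS fraction.

library(telomark)

counts <- run_count("results/cohort", out_file = "results/counts.tsv",
                    mapper = "exact")

cat(sprintf("counted %d samples -> results/counts.tsv\n", nrow(counts)))
cat("\nRMUS by mark and role (mean):\n")
print(aggregate(rmus ~ mark + role, counts, mean))
cat("\ntelomeric read fractions span ",
    sprintf("%.2e .. %.2e", min((counts$TEL_C + counts$TEL_G) / counts$mapping_reads),
            max((counts$TEL_C + counts$TEL_G) / counts$mapping_reads)), "\n")
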