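#!/usr/bin/env Rscript

# Stage 1 -- simulate the study cohort.
#
# Builds one synthetic genome (2 x 200 kb, 3,750-bp telomeres, ITSs and
# 178-bp satellite blocks embedded in single-copy background) and a cohort
# of replicate ChIP-seq studies for three marks:
#   euchromatic_like     IP favours single-copy background (weight 3)
#   heterochromatic_like IP favours ITSs and satellite blocks (weight 3)
#   null_mark            IP sampled exactly like the input
# Each study contributes one input and one IP FASTQ of 50,000 100-nt reads.
# Everything lands under results/cohort/ with an MD5 manifest.

library(telomark)

out <- "results/cohort"
cfg <- simulate_config(
  genome = genome_spec(seed = 2026L),
  marks = list(euchromatic_like = mark_profile(background = 3),
               heterochromatic_like = mark_profile(its = 3, satellite = 3),
               null_mark = mark_profile()),
  n_studies = 6L, n_reads = 50000L)

manifest <- run_simulate(out, cfg, seed = 2026L, force = TRUE)

cat(sprintf("wrote %d files under %s (genome, truth, %d FASTQ samples)\n",
            length(manifest$checksums), out, length(manifest$samples)))
cat("genome seed:", manifest$genome_seed, "\n")
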