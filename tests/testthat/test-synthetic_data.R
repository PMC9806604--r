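test_that("default-scale telomeres carry floor(3750/7) - 4 overlapping motifs", {
  g <- build_genome(genome_spec(seed = 1))
  iv <- g$truth$intervals
  tel <- iv[iv$label == "telomere"]
  per_end <- pmax(tel$n_TEL_C, tel$n_TEL_G)
  expect_true(all(per_end == floor(3750 / 7) - 4L))   # 531
  # verified independently by scanning the left terminal tract
  left <- as.character(Biostrings::subseq(g$genome[[1]], 1, 3750))
  expect_identical(oracle_count(left, strrep("CCCTAAA", 5)), 531L)
})

test_that("genome construction is deterministic in the seed", {
  g1 <- build_genome(tiny_spec(seed = 42))
  g2 <- build_genome(tiny_spec(seed = 42))
  expect_identical(as.character(g1$genome), as.character(g2$genome))
  expect_identical(as.data.frame(g1$truth$intervals),
                   as.data.frame(g2$truth$intervals))
  g3 <- build_genome(tiny_spec(seed = 43))
  expect_false(identical(as.character(g1$genome), as.character(g3$genome)))
  # same architecture either way
  expect_identical(table(g1$truth$intervals$label),
                   table(g3$truth$intervals$label))
})

test_that("truth intervals tile each chromosome and counts survive a rescan", {
  withr::local_seed(2024)
  classes <- default_motif_classes()
  for (rep_i in 1:20) {
    sp <- tiny_spec(seed = sample.int(10^6, 1),
                    its_count = sample(0:4, 1),
                    satellite_block_count = sample(0:2, 1),
                    its_mean_perfect_stretch_repeats = sample(c(1.5, 3, 5), 1),
                    its_degeneracy_rate = runif(1, 0, 0.3))
    g <- build_genome(sp)
    iv <- g$truth$intervals
    for (nm in names(g$genome)) {
      sel <- as.character(GenomicRanges::seqnames(iv)) == nm
      expect_identical(sum(GenomicRanges::width(iv[sel])),
                       sp$chromosome_length_bp)
      expect_identical(
        GenomicRanges::start(iv[sel])[-1],
        GenomicRanges::end(iv[sel])[-sum(sel)] + 1L)
      chrom <- as.character(g$genome[[nm]])
      starts <- GenomicRanges::start(iv[sel])
      for (k in names(classes)) {
        pos <- oracle_positions(chrom, classes[[k]])
        want <- tabulate(findInterval(pos, starts), nbins = sum(sel))
        expect_identical(S4Vectors::mcols(iv[sel])[[paste0("n_", k)]],
                         as.integer(want))
      }
    }
  }
})

test_that("infeasible packing and invalid specs are rejected", {
  expect_error(build_genome(tiny_spec(seed = 1, satellite_block_count = 4,
                                      satellite_repeats_per_block = 100)),
               "infeasible")
  expect_error(genome_spec(telomere_length_bp = 20), "telomere_length_bp")
  expect_error(genome_spec(chromosome_length_bp = 7000,
                           telomere_length_bp = 3750), "exceed")
})

test_that("a repeat-free spec yields only telomere and background intervals", {
  g <- build_genome(tiny_spec(seed = 4, its_count = 0,
                              satellite_block_count = 0))
  expect_setequal(unique(g$truth$intervals$label),
                  c("telomere", "background"))
})

test_that("the satellite monomer carries Cen1 and Cen2 exactly once", {
  mono <- satellite_monomer()
  expect_identical(nchar(mono), 178L)
  cls <- default_motif_classes()
  expect_identical(oracle_count(strrep(mono, 3), cls[["CEN1"]]), 3L)
  expect_identical(oracle_count(strrep(mono, 3), cls[["CEN2"]]), 3L)
  expect_identical(substr(mono, 21, 43), unname(cls[["CEN1"]]))
  expect_identical(substr(mono, 101, 123), unname(cls[["CEN2"]]))
})

test_that("input read starts are uniform across the genome", {
  g <- build_genome(tiny_spec(seed = 6))
  rd <- simulate_sample(g$genome, g$truth, role = "input",
                        n_reads = 20000, seed = 60)
  org <- read_origin(rd)
  # map starts onto a genome-wide coordinate and bin into 10 equal bins
  L <- 30000L - 100L + 1L
  gpos <- org$start0 + ifelse(org$chrom == "chr2", L, 0L)
  counts <- tabulate(findInterval(gpos, seq(0, 2 * L, length.out = 11),
                                  rightmost.closed = TRUE), nbins = 10)
  p <- stats::chisq.test(counts)$p.value
  expect_gt(p, 0.001)
})

test_that("simulated reads match their encoded origin coordinates", {
  g <- build_genome(tiny_spec(seed = 8))
  rd <- simulate_sample(g$genome, g$truth, mark_profile(telomere = 2),
                        role = "IP", n_reads = 500, seed = 80)
  org <- read_origin(rd)
  expect_identical(nrow(org), 500L)
  expect_true(all(org$label %in% c("telomere", "ITS", "satellite",
                                   "background")))
  for (i in sample(500, 25)) {
    win <- as.character(Biostrings::subseq(g$genome[[org$chrom[i]]],
                                           org$start0[i] + 1L,
                                           org$start0[i] + 100L))
    if (org$strand[i] == "-") win <- oracle_revcomp(win)
    expect_identical(as.character(rd[[i]]), win)
  }
  # same seed, same reads
  rd2 <- simulate_sample(g$genome, g$truth, mark_profile(telomere = 2),
                         role = "IP", n_reads = 500, seed = 80)
  expect_identical(as.character(rd2), as.character(rd))
})

test_that("both telomeric strand classes arise through the strand flip", {
  g <- build_genome(tiny_spec(seed = 10, its_count = 0,
                              satellite_block_count = 0))
  rd <- simulate_sample(g$genome, g$truth, mark_profile(telomere = 5),
                        role = "IP", n_reads = 4000, seed = 100)
  hits <- classify_reads(rd, default_motif_classes()[c("TEL_C", "TEL_G")])
  org <- read_origin(rd)
  c_reads <- org[hits[, "TEL_C"], ]
  # C-strand motif reads come from the left array read forward and from the
  # right array read in reverse complement
  expect_true(any(c_reads$strand == "+" & c_reads$start0 < 1000))
  expect_true(any(c_reads$strand == "-" & c_reads$start0 > 29000))
})

test_that("a null profile leaves every class enrichment near one", {
  g <- build_genome(genome_spec(seed = 12))
  inp <- simulate_sample(g$genome, g$truth, role = "input",
                         n_reads = 50000, seed = 120)
  ip <- simulate_sample(g$genome, g$truth, mark_profile(), role = "IP",
                        n_reads = 50000, seed = 121)
  ci <- count_sample(ip, study_id = "s", mark = "null", role = "IP",
                     mapper = "none")
  cn <- count_sample(inp, study_id = "s", mark = "null", role = "input",
                     mapper = "none")
  for (cl in c("TEL_C", "TEL_G", "CEN1", "CEN2")) {
    e <- enrichment_vs_genome(ci, cn, cl)
    expect_gt(e, 0.8); expect_lt(e, 1.25)
  }
})

test_that("ITS-origin contamination of telomeric reads sits in the stated regime", {
  g <- build_genome(genome_spec(seed = 1))
  classes <- default_motif_classes()
  internal <- count_internal_motifs(g$genome, classes[["TEL_C"]],
                                    truth_telomere_mask(g$truth))
  telomeric <- sum(g$truth$intervals$n_TEL_C[
    g$truth$intervals$label == "telomere"]) +
    sum(g$truth$intervals$n_TEL_G[g$truth$intervals$label == "telomere"])
  predicted <- its_contamination_percent(internal, telomeric)
  rd <- simulate_sample(g$genome, g$truth, role = "input",
                        n_reads = 150000, seed = 13)
  hits <- classify_reads(rd, classes[c("TEL_C", "TEL_G")])
  tel_hit <- hits[, 1] | hits[, 2]
  org <- read_origin(rd)
  observed <- 100 * sum(tel_hit & org$label == "ITS") / sum(tel_hit)
  # occurrence arithmetic predicts the order of magnitude of the read-level
  # fraction (isolated internal stretches admit more read placements per
  # occurrence than array-internal ones, so only rough agreement is expected)
  expect_lt(observed, 5)
  expect_lt(abs(log10((observed + 0.01) / (predicted + 0.01))), 1)
})

test_that("removing degeneracy turns ITSs into perfect arrays with more motifs", {
  base <- tiny_spec(seed = 21, its_count = 3,
                    its_mean_perfect_stretch_repeats = 3,
                    its_degeneracy_rate = 0.25)
  g_deg <- build_genome(base)
  base$its_degeneracy_rate <- 0
  g_per <- build_genome(base)
  tel_c <- strrep("CCCTAAA", 5)
  n_deg <- count_internal_motifs(g_deg$genome, tel_c,
                                 truth_telomere_mask(g_deg$truth))
  n_per <- count_internal_motifs(g_per$genome, tel_c,
                                 truth_telomere_mask(g_per$truth))
  expect_gt(n_per, n_deg)
})

test_that("truth serialisation round-trips through BED and JSON", {
  g <- build_genome(tiny_spec(seed = 30))
  bed <- tempfile(fileext = ".bed"); json <- tempfile(fileext = ".json")
  write_truth(g$truth, bed, json)
  back <- read_truth(json)
  expect_identical(as.data.frame(back$intervals),
                   as.data.frame(g$truth$intervals))
  expect_identical(unclass(back$spec), unclass(g$truth$spec))
  rt <- rtracklayer::import(bed)
  expect_identical(length(rt), length(g$truth$intervals))
  expect_identical(GenomicRanges::start(rt),
                   GenomicRanges::start(g$truth$intervals))
  expect_identical(rt$name, g$truth$intervals$label)
})
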