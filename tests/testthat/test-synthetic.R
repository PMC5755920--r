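test_that("genome generation is seed-reproducible with the planted density ratio", {
  spec <- genome_spec(chrom_length = 100000L, n_islands = 10L,
                      island_meanlog = log(1000), island_sdlog = 0,
                      island_min = 1000L, cpg_density_multiplier = 5,
                      motifs = NULL)
  g1 <- generate_genome(spec, seed = 61)
  g2 <- generate_genome(spec, seed = 61)
  expect_equal(as.character(g1$genome), as.character(g2$genome))
  expect_equal(g1$truth, g2$truth)
  expect_equal(sum(g1$truth$end - g1$truth$start), 10000L)

  cg <- enumerate_cpg_sites(g1$genome)$chr1
  island_bp <- sum(g1$truth$end - g1$truth$start)
  in_island <- rep(FALSE, length(cg))
  for (i in seq_len(nrow(g1$truth)))
    in_island <- in_island | (cg >= g1$truth$start[i] & cg < g1$truth$end[i])
  dens_island <- sum(in_island) / island_bp
  dens_bg <- sum(!in_island) / (100000 - island_bp)
  expect_gte(dens_island / dens_bg, 3.5)
  expect_lte(dens_island / dens_bg, 6.5)

  # infeasible layout errors
  expect_error(generate_genome(genome_spec(chrom_length = 5000L, n_islands = 10L),
                               seed = 1), "infeasible")
})

test_that("simulated methylomes are bimodal with realistic coverage loss", {
  spec <- genome_spec(chrom_length = 60000L, n_islands = 6L, motifs = NULL)
  gen <- generate_genome(spec, seed = 62)
  deep <- simulate_methylome(gen$genome, gen$truth,
                             methylome_spec(coverage_mean = 200), seed = 63)
  tr <- deep$truth_rates
  expect_equal(tr$pos, unlist(lapply(enumerate_cpg_sites(gen$genome), identity),
                              use.names = FALSE))
  # island CpGs draw from Beta(1,9): mean observed rate near 10%
  island_rates <- deep$track$rate[match(tr$pos[tr$state == "hypo"],
                                        deep$track$pos)]
  expect_lt(abs(mean(island_rates, na.rm = TRUE) - 10), 3)
  bg_rates <- deep$track$rate[match(tr$pos[tr$state == "hyper"], deep$track$pos)]
  expect_lt(abs(mean(bg_rates, na.rm = TRUE) - 90), 3)

  # default mean-8 coverage loses a nonzero fraction of dyads at the 5x filter
  shallow <- simulate_methylome(gen$genome, gen$truth, methylome_spec(), seed = 64)
  kept <- nrow(filter_coverage(shallow$track))
  expect_lt(kept, nrow(shallow$truth_rates))
  expect_gt(kept, 0.5 * nrow(shallow$truth_rates))
})

test_that("the domain caller recovers planted islands at deep coverage", {
  gen <- generate_genome(genome_spec(chrom_length = 200000L, n_islands = 10L),
                         seed = 21)
  sim <- simulate_methylome(gen$genome, gen$truth,
                            methylome_spec(coverage_mean = 30), seed = 22)
  res <- call_all(filter_coverage(sim$track), gen$genome)
  truth_ir <- IRanges::IRanges(gen$truth$start + 1L, gen$truth$end)
  hypo_ir <- IRanges::IRanges(res$hypo$start + 1L, res$hypo$end)
  recovered <- sum(IRanges::width(IRanges::intersect(truth_ir, hypo_ir)))
  expect_gte(recovered / sum(IRanges::width(truth_ir)), 0.9)
})

test_that("MspI digestion cuts C^CGG and tiles the genome", {
  g <- Biostrings::DNAStringSet(c(toy = "TTCCGGAAACCGGTT"))
  fr <- msp1_capture(g)
  expect_equal(fr$start, c(0L, 3L, 10L))
  expect_equal(fr$end, c(3L, 10L, 15L))
  seqs <- substring(as.character(g), fr$start + 1, fr$end)
  expect_equal(seqs[2], "CGGAAAC")
  expect_equal(paste(seqs, collapse = ""), unname(as.character(g)))

  # no CCGG: a single unretained fragment spanning the chromosome
  none <- msp1_capture(Biostrings::DNAStringSet(c(x = "AAATTTAAA")))
  expect_equal(nrow(none), 1L)
  expect_equal(sum(none$retained), 0L)

  # random-sequence tiling property
  set.seed(67)
  s <- paste(sample(c("A", "C", "G", "T"), 20000, TRUE), collapse = "")
  fr <- msp1_capture(Biostrings::DNAStringSet(c(chr = s)))
  expect_equal(paste(substring(s, fr$start + 1, fr$end), collapse = ""), s)
  expect_true(all(fr$retained == (fr$length >= 40 & fr$length <= 220)))
})

test_that("size selection keeps [40,220] bp and reports adapter-extended lengths", {
  seg <- function(n) paste(rep("A", n), collapse = "")
  # fragment lengths between cuts: 4 + run length
  s <- paste0(seg(10), "CCGG", seg(35), "CCGG", seg(216), "CCGG", seg(36),
              "CCGG", seg(217), "CCGG", seg(10))
  fr <- msp1_capture(Biostrings::DNAStringSet(c(chr = s)))
  internal <- fr[-c(1, nrow(fr)), ]
  expect_equal(internal$length, c(39L, 220L, 40L, 221L))
  expect_equal(internal$retained, c(FALSE, TRUE, TRUE, FALSE))
  expect_equal(internal$extended_length[internal$retained], c(364L, 184L))
})

test_that("integration models produce their signature readouts", {
  gen <- generate_genome(genome_spec(chrom_length = 100000L, n_islands = 10L),
                         seed = 71)
  sim <- simulate_methylome(gen$genome, gen$truth,
                            methylome_spec(coverage_mean = 30), seed = 72)
  frags <- tile_fragments(gen$genome)

  # maintenance with zero gain: every ectopic call fully unmethylated
  fc <- simulate_integration(frags, sim$truth_rates, "unmethylated",
                             integration_model("maintenance", gamma = 0), seed = 73)
  expect_true(all(fc$n_meth == 0L))
  # determinism
  fc2 <- simulate_integration(frags, sim$truth_rates, "unmethylated",
                              integration_model("maintenance", gamma = 0), seed = 73)
  expect_equal(fc, fc2)

  # default hypermethylation drives both libraries to the same high-rate
  # histogram shape regardless of starting state
  track <- filter_coverage(sim$track)
  h <- lapply(c("unmethylated", "premethylated"), function(lib) {
    fci <- simulate_integration(frags, sim$truth_rates, lib,
                                integration_model("default_hypermethylation"),
                                seed = 74)
    m <- pool_matched_cpgs(match_cpgs(fci, track))
    rate_histogram(m$ectopic_rate)$count
  })
  tv <- sum(abs(h[[1]] / sum(h[[1]]) - h[[2]] / sum(h[[2]]))) / 2
  expect_lt(tv, 0.1)
  expect_gt(sum(h[[1]][81:100]) / sum(h[[1]]), 0.8)
})

test_that("noise-free traces encode rates and editing exactly", {
  st <- simulate_trace(75, editing = 100, noise = 0)
  expect_equal(methylation_rate(st$peaks$C[1], st$peaks$T[1]), 75.0)
  st2 <- simulate_trace(c(10, 20), editing = 50, noise = 0)
  e <- editing_rate(st2$peaks, st2$pam_sites)
  expect_equal(e$locus_rate, 50.0)
  # reproducible under seed
  a <- simulate_trace(runif(5, 0, 100), 60, noise = 0.1, seed = 8)
  b <- simulate_trace(a$truth$rates, 60, noise = 0.1, seed = 8)
  expect_equal(a$peaks, b$peaks)
})

test_that("tiled fragments cover every genomic CpG exactly once", {
  gen <- generate_genome(genome_spec(chrom_length = 30000L, n_islands = 3L),
                         seed = 75)
  fr <- tile_fragments(gen$genome, width = 150L)
  expect_equal(sum(fr$length), 30000L)
  expect_true(all(fr$retained))
  cg <- enumerate_cpg_sites(gen$genome)$chr1
  hits <- vapply(cg, function(p) sum(fr$start <= p & fr$end > p), numeric(1))
  expect_true(all(hits == 1))
})
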