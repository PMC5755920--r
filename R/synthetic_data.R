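#' Synthetic genome specification
#'
#' Describes an artificial genome emulating the structure the pipeline is
#' built for: a hypermethylated background in which CpG-dense
#' hypomethylated islands are embedded. CpG density is controlled directly
#' (CG dinucleotides are planted at a per-position rate) because CpG
#' density is the biological signal of interest; short sequence motifs can
#' additionally be planted with island-vs-background enrichment to give the
#' CpG-masked classifier a non-CpG signal to find.
#'
#' Realism defaults: background CpG density 10/kb with a 5-fold island
#' enrichment (CpG islands versus depleted vertebrate background), island
#' lengths lognormal around 800 bp, spacers around 3 kb, background GC 0.40,
#' and one planted 6-bp motif (`TGACCT`, a nuclear-receptor-like half-site
#' containing no CG) at ~4 island occurrences per kb with 5-fold
#' enrichment over background.
#'
#' @param n_chrom,chrom_length chromosome count and length (bp).
#' @param gc_background background GC fraction.
#' @param n_islands islands per chromosome.
#' @param island_meanlog,island_sdlog,island_min lognormal island-length
#'   distribution (bp).
#' @param spacing_meanlog,spacing_sdlog,spacing_min lognormal inter-island
#'   spacing (bp).
#' @param cpg_rate_background CG dinucleotides planted per bp of background.
#' @param cpg_density_multiplier island-over-background CpG density ratio.
#' @param motifs data.frame with columns `motif` (CG-free string),
#'   `island_rate` (occurrences per bp in islands) and `enrichment`
#'   (island/background rate ratio); NULL for none.
#' @return a `genome_spec` list.
#' @export
genome_spec <- function(n_chrom = 1L, chrom_length = 200000L,
                        gc_background = 0.40, n_islands = 10L,
                        island_meanlog = log(800), island_sdlog = 0.4,
                        island_min = 200L,
                        spacing_meanlog = log(3000), spacing_sdlog = 0.5,
                        spacing_min = 500L,
                        cpg_rate_background = 0.01,
                        cpg_density_multiplier = 5,
                        motifs = default_motifs()) {
  stopifnot(cpg_rate_background > 0, cpg_density_multiplier > 0,
            chrom_length > 0, n_islands >= 0)
  structure(as.list(environment()), class = "genome_spec")
}

#' @rdname genome_spec
#' @export
default_motifs <- function() {
  data.frame(motif = "TGACCT", island_rate = 0.004, enrichment = 5)
}

# iid sequence with CGs removed, then CGs planted at `p_cg` per position,
# then motifs written last (so island motifs are not destroyed by planting)
make_seq <- function(len, gc, p_cg, motifs = NULL) {
  probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  x <- sample(c("A", "C", "G", "T"), len, replace = TRUE, prob = probs)
  cg <- which(x[-len] == "C" & x[-1] == "G")
  if (length(cg)) x[cg + 1L] <- "T"
  n_cg <- stats::rbinom(1, len - 1L, p_cg)
  if (n_cg > 0) {
    pos <- sort(sample.int(len - 1L, min(n_cg, len - 1L)))
    pos <- pos[c(TRUE, diff(pos) >= 2L)]
    x[pos] <- "C"; x[pos + 1L] <- "G"
  }
  if (!is.null(motifs) && nrow(motifs)) {
    for (i in seq_len(nrow(motifs))) {
      m <- strsplit(motifs$motif[i], NULL)[[1]]
      lm <- length(m)
      if (len <= lm) next
      n_m <- stats::rbinom(1, len - lm, motifs$rate[i])
      if (n_m > 0) {
        at <- sample.int(len - lm, min(n_m, len - lm))
        for (a in at) x[a:(a + lm - 1L)] <- m
      }
    }
  }
  paste(x, collapse = "")
}

#' Generate a synthetic genome with hypomethylated islands
#'
#' Lays out each chromosome as alternating background spacers and islands,
#' builds the sequence segment by segment with the spec's CpG densities and
#' motif rates, and returns both the sequence and the ground-truth island
#' intervals. Deterministic under `seed`.
#'
#' @param spec a [genome_spec()].
#' @param seed integer seed, or NULL to use the current RNG state.
#' @return list with `genome` ([Biostrings::DNAStringSet]) and `truth`
#'   (a [region_set()] of island intervals, named `island`).
#' @export
generate_genome <- function(spec = genome_spec(), seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  p_island <- spec$cpg_rate_background * spec$cpg_density_multiplier
  im <- if (is.null(spec$motifs)) NULL else
    data.frame(motif = spec$motifs$motif, rate = spec$motifs$island_rate)
  bm <- if (is.null(spec$motifs)) NULL else
    data.frame(motif = spec$motifs$motif,
               rate = spec$motifs$island_rate / spec$motifs$enrichment)
  chroms <- character(spec$n_chrom)
  truth <- list()
  for (ci in seq_len(spec$n_chrom)) {
    ch <- paste0("chr", ci)
    il <- pmax(round(stats::rlnorm(spec$n_islands, spec$island_meanlog,
                                   spec$island_sdlog)), spec$island_min)
    sp <- pmax(round(stats::rlnorm(spec$n_islands + 1L, spec$spacing_meanlog,
                                   spec$spacing_sdlog)), spec$spacing_min)
    if (sum(il) + sum(sp) > spec$chrom_length)
      stop("infeasible layout: islands and spacers exceed chromosome length")
    segs <- character(0)
    pos <- 0L
    for (k in seq_len(spec$n_islands)) {
      segs <- c(segs, make_seq(sp[k], spec$gc_background,
                               spec$cpg_rate_background, bm))
      pos <- pos + sp[k]
      segs <- c(segs, make_seq(il[k], spec$gc_background, p_island, im))
      truth[[length(truth) + 1L]] <- data.frame(chrom = ch, start = pos,
                                                end = pos + il[k])
      pos <- pos + il[k]
    }
    tail_len <- spec$chrom_length - pos
    segs <- c(segs, make_seq(max(tail_len, 1L), spec$gc_background,
                             spec$cpg_rate_background, bm))
    chroms[ci] <- substr(paste(segs, collapse = ""), 1L, spec$chrom_length)
  }
  g <- Biostrings::DNAStringSet(chroms)
  names(g) <- paste0("chr", seq_len(spec$n_chrom))
  tr <- do.call(rbind, truth)
  truth_rs <- if (is.null(tr)) region_set(character(), integer(), integer())
              else region_set(tr$chrom, tr$start, tr$end,
                              name = rep("island", nrow(tr)))
  list(genome = g, truth = truth_rs)
}

#' Synthetic methylome specification
#'
#' Bimodal per-CpG methylation: island (hypomethylated) CpGs draw their
#' true rate from Beta(1, 9) (mean 10%), background (hypermethylated) CpGs
#' from Beta(9, 1) (mean 90%), matching the strong skew of vertebrate
#' methylomes towards 0%/100%. Sequencing coverage is negative-binomial
#' with mean 8 (the pipeline's post-filter mean coverage) and the observed
#' methylated count is binomial in the true rate, so a realistic fraction
#' of dyads falls below the 5x validity threshold.
#'
#' @param hypo_shape,hyper_shape Beta shape pairs for island/background
#'   true rates.
#' @param coverage_mean,coverage_size negative-binomial coverage (mu, size).
#' @return a `methylome_spec` list.
#' @export
methylome_spec <- function(hypo_shape = c(1, 9), hyper_shape = c(9, 1),
                           coverage_mean = 8, coverage_size = 4) {
  stopifnot(all(hypo_shape > 0), all(hyper_shape > 0), coverage_mean >= 1)
  structure(as.list(environment()), class = "methylome_spec")
}

#' Simulate a whole-genome bisulfite methylome
#'
#' Draws a true methylation rate for every genomic CpG (state taken from
#' the truth islands), then coverage and methylated counts, and returns
#' both the observable call track (dyads with zero coverage are absent,
#' as in real extractor output) and the per-CpG ground truth.
#'
#' @param genome a [Biostrings::DNAStringSet].
#' @param truth island [region_set()] (CpGs inside are hypomethylated).
#' @param spec a [methylome_spec()].
#' @param seed integer seed or NULL.
#' @return list with `track` (a [methylation_track()]) and `truth_rates`
#'   (data.frame `chrom`, `pos`, `state`, `true_rate`).
#' @export
simulate_methylome <- function(genome, truth, spec = methylome_spec(),
                               seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  sites <- enumerate_cpg_sites(genome)
  rows <- lapply(names(sites), function(ch) {
    pos <- sites[[ch]]
    if (!length(pos)) return(NULL)
    in_island <- rep(FALSE, length(pos))
    tr <- truth[truth$chrom == ch, , drop = FALSE]
    if (nrow(tr)) {
      ov <- IRanges::findOverlaps(
        IRanges::IRanges(pos + 1L, pos + 2L),
        IRanges::IRanges(tr$start + 1L, tr$end))
      in_island[unique(S4Vectors::queryHits(ov))] <- TRUE
    }
    n <- length(pos)
    rate <- numeric(n)
    rate[in_island] <- stats::rbeta(sum(in_island), spec$hypo_shape[1], spec$hypo_shape[2])
    rate[!in_island] <- stats::rbeta(sum(!in_island), spec$hyper_shape[1], spec$hyper_shape[2])
    cov <- stats::rnbinom(n, mu = spec$coverage_mean, size = spec$coverage_size)
    n_meth <- stats::rbinom(n, cov, rate)
    data.frame(chrom = ch, pos = pos, state = ifelse(in_island, "hypo", "hyper"),
               true_rate = 100 * rate, cov = cov, n_meth = n_meth)
  })
  df <- do.call(rbind, rows)
  obs <- df[df$cov > 0, , drop = FALSE]
  list(track = methylation_track(obs$chrom, obs$pos, obs$n_meth,
                                 obs$cov - obs$n_meth),
       truth_rates = df[c("chrom", "pos", "state", "true_rate")])
}

#' In-silico MspI digestion with RRBS-style size selection
#'
#' Cuts every CCGG occurrence between the first C and the CGG (the
#' enzyme's C^CGG convention, occurrences taken left to right) and reports
#' all resulting fragments; the unfiltered fragments tile each chromosome
#' exactly. Fragments whose length lies in `[size_min, size_max]` are
#' marked retained, with the adapter-extended length (`length +
#' adapter_extension`) reported as a library-molecule size.
#'
#' @param genome a [Biostrings::DNAStringSet].
#' @param size_min,size_max retained size window in bp (defaults 40, 220).
#' @param adapter_extension added length after adapter ligation (default
#'   144, so 40-220 bp inserts become 184-364 bp molecules).
#' @return data.frame `id`, `chrom`, `start`, `end`, `length`, `retained`,
#'   `extended_length`.
#' @export
msp1_capture <- function(genome, size_min = 40L, size_max = 220L,
                         adapter_extension = 144L) {
  rows <- lapply(names(genome), function(ch) {
    s <- genome[[ch]]
    hits <- Biostrings::matchPattern("CCGG", s)
    cuts <- as.integer(BiocGenerics::start(hits))  # 1-based start => 0-based cut after C
    bounds <- unique(c(0L, cuts, length(s)))
    if (length(bounds) < 2) bounds <- c(0L, length(s))
    data.frame(chrom = ch, start = bounds[-length(bounds)], end = bounds[-1])
  })
  df <- do.call(rbind, rows)
  df <- df[df$end > df$start, , drop = FALSE]
  df$length <- df$end - df$start
  df$retained <- df$length >= size_min & df$length <= size_max
  df$extended_length <- df$length + adapter_extension
  df <- cbind(id = paste0("frag", seq_len(nrow(df))), df)
  rownames(df) <- NULL
  df
}

#' Integration model for ectopic methylation simulation
#'
#' Three competing generative models for the methylation state of a
#' reintegrated fragment CpG:
#' * `maintenance` — the artificially conferred library state persists;
#'   each CpG flips fully (0 to 100 or vice versa) with probability
#'   `gamma` (gain, from the unmethylated library) or `delta` (loss, from
#'   the premethylated library), independent of the endogenous state.
#' * `sequence_determined` — the ectopic rate re-establishes the
#'   endogenous true rate up to Gaussian noise of `noise` points.
#' * `default_hypermethylation` — every CpG is driven towards full
#'   methylation (Beta(9,1)) regardless of library.
#'
#' @param mode one of the three model names.
#' @param delta,gamma per-CpG loss/gain probabilities (default 0.02; the
#'   loss rate is a free parameter, not calibrated to any measurement).
#' @param noise Gaussian noise scale in percentage points (default 5).
#' @return an `integration_model` list.
#' @export
integration_model <- function(mode = c("maintenance", "sequence_determined",
                                       "default_hypermethylation"),
                              delta = 0.02, gamma = 0.02, noise = 5) {
  stopifnot(delta >= 0, delta <= 1, gamma >= 0, gamma <= 1, noise >= 0)
  structure(list(mode = match.arg(mode), delta = delta, gamma = gamma,
                 noise = noise), class = "integration_model")
}

#' Simulate ectopic methylation readouts of integrated fragments
#'
#' For every retained fragment and every genomic CpG it carries, draws the
#' ectopic true rate under the chosen [integration_model()], then samples
#' sequencing counts at pooled-embryo coverage (negative binomial, default
#' mean 250 as in deep amplicon pools).
#'
#' @param fragments output of [msp1_capture()] (only `retained` rows used).
#' @param truth_rates per-CpG truth from [simulate_methylome()].
#' @param library `"unmethylated"` (PCR-amplified) or `"premethylated"`
#'   (M.SssI-treated).
#' @param model an [integration_model()].
#' @param coverage_mean,coverage_size ectopic sequencing coverage (NB).
#' @param seed integer seed or NULL.
#' @return a fragment call data.frame as read by [match_cpgs()].
#' @export
simulate_integration <- function(fragments, truth_rates,
                                 library = c("unmethylated", "premethylated"),
                                 model = integration_model(),
                                 coverage_mean = 250, coverage_size = 5,
                                 seed = NULL) {
  library <- match.arg(library)
  if (!is.null(seed)) withr::local_seed(seed)
  fr <- fragments[fragments$retained, , drop = FALSE]
  pieces <- lapply(unique(fr$chrom), function(ch) {
    f <- fr[fr$chrom == ch, , drop = FALSE]
    tr <- truth_rates[truth_rates$chrom == ch, , drop = FALSE]
    if (!nrow(f) || !nrow(tr)) return(NULL)
    ov <- IRanges::findOverlaps(IRanges::IRanges(tr$pos + 1L, tr$pos + 1L),
                                IRanges::IRanges(f$start + 1L, f$end))
    if (!length(ov)) return(NULL)
    qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
    data.frame(id = f$id[si], chrom = ch, start = f$start[si], end = f$end[si],
               offset = tr$pos[qi] - f$start[si], endo_true = tr$true_rate[qi])
  })
  df <- do.call(rbind, pieces)
  if (is.null(df) || !nrow(df))
    return(data.frame(id = character(), chrom = character(), start = integer(),
                      end = integer(), offset = integer(), n_meth = integer(),
                      n_unmeth = integer(), library = character()))
  n <- nrow(df)
  base <- if (library == "unmethylated") 0 else 100
  rate <- switch(model$mode,
    maintenance = {
      p_flip <- if (library == "unmethylated") model$gamma else model$delta
      flip <- stats::runif(n) < p_flip
      ifelse(flip, 100 - base, base)
    },
    sequence_determined =
      pmin(pmax(df$endo_true + stats::rnorm(n, 0, model$noise), 0), 100),
    default_hypermethylation = 100 * stats::rbeta(n, 9, 1))
  cov <- pmax(stats::rnbinom(n, mu = coverage_mean, size = coverage_size), 1L)
  n_meth <- stats::rbinom(n, cov, rate / 100)
  out <- data.frame(id = df$id, chrom = df$chrom, start = df$start, end = df$end,
                    offset = df$offset, n_meth = n_meth, n_unmeth = cov - n_meth,
                    library = library, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Simulate a Sanger peak-height table
#'
#' Builds a peak table for an edited locus: only edited alleles carry the
#' installed methylation, so the C/T heights at each CpG row encode the
#' allele mixture `rate x editing / 100` and editing-normalization of the
#' raw trace rate recovers the per-allele truth. C/G heights at PAM rows
#' encode the editing rate itself. Multiplicative lognormal noise of scale
#' `noise` is applied to every nonzero height; at `noise = 0` and full
#' editing the raw height-ratio formula returns the true rates exactly.
#'
#' @param true_rates per-CpG true methylation rates on edited alleles, in
#'   percent.
#' @param editing true editing rate in percent.
#' @param n_pam number of annotated PAM third-base rows (default 6).
#' @param noise multiplicative noise scale (sd of log-heights; default 0).
#' @param base_height nominal full peak height (default 1000).
#' @param seed integer seed or NULL.
#' @return list with `peaks` (a `peak_table`), `cpg_sites`, `pam_sites`,
#'   and `truth`.
#' @export
simulate_trace <- function(true_rates, editing, n_pam = 6L, noise = 0,
                           base_height = 1000, seed = NULL) {
  stopifnot(all(true_rates >= 0 & true_rates <= 100),
            editing >= 0, editing <= 100)
  if (!is.null(seed)) withr::local_seed(seed)
  n <- length(true_rates)
  jitter <- function(k) exp(stats::rnorm(k, 0, noise))
  cpg_pos <- seq_len(n)
  pam_pos <- n + seq_len(n_pam)
  df <- data.frame(position = c(cpg_pos, pam_pos),
                   A = 0, C = 0, G = 0, T = 0)
  mix <- (true_rates / 100) * (editing / 100)
  df$C[cpg_pos] <- base_height * mix * jitter(n)
  df$T[cpg_pos] <- base_height * (1 - mix) * jitter(n)
  df$C[pam_pos] <- base_height * (editing / 100) * jitter(n_pam)
  df$G[pam_pos] <- base_height * (1 - editing / 100) * jitter(n_pam)
  list(peaks = peak_table(df), cpg_sites = cpg_pos, pam_sites = pam_pos,
       truth = list(rates = true_rates, editing = editing))
}

#' Tile a genome into fixed-width integration windows
#'
#' An idealized fragment source for integration simulations: non-overlapping
#' windows covering every chromosome (all marked retained), so that every
#' genomic CpG is carried by exactly one fragment. Use [msp1_capture()]
#' instead when the enzymatic capture bias itself is under study.
#'
#' @param genome a [Biostrings::DNAStringSet].
#' @param width window width in bp (default 150).
#' @return a fragment table in the same form as [msp1_capture()].
#' @export
tile_fragments <- function(genome, width = 150L) {
  rows <- lapply(names(genome), function(ch) {
    len <- Biostrings::width(genome[names(genome) == ch])[1]
    start <- seq(0L, len - 1L, by = width)
    data.frame(chrom = ch, start = start, end = pmin(start + width, len))
  })
  df <- do.call(rbind, rows)
  df$length <- df$end - df$start
  df$retained <- TRUE
  df$extended_length <- df$length
  cbind(id = paste0("tile", seq_len(nrow(df))), df)
}

#' Study-scale labeled domain sequences for classifier evaluation
#'
#' Draws hypomethylated-island-like and hypermethylated-background-like
#' sequences directly (2000 of each by default) with a shared length
#' distribution, so that CpG density and the planted motif are the only
#' class differences — the synthetic stand-in for classifying called
#' domains when the real methylome is unavailable.
#'
#' @param n_hypo,n_hyper sequences per class.
#' @param spec a [genome_spec()] supplying densities, GC and motifs.
#' @param seed integer seed or NULL.
#' @return list of two [Biostrings::DNAStringSet]s, `hypo` and `hyper`.
#' @export
simulate_domain_sequences <- function(n_hypo = 2000L, n_hyper = 2000L,
                                      spec = genome_spec(), seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  p_island <- spec$cpg_rate_background * spec$cpg_density_multiplier
  im <- if (is.null(spec$motifs)) NULL else
    data.frame(motif = spec$motifs$motif, rate = spec$motifs$island_rate)
  bm <- if (is.null(spec$motifs)) NULL else
    data.frame(motif = spec$motifs$motif,
               rate = spec$motifs$island_rate / spec$motifs$enrichment)
  draw_len <- function(k) pmin(pmax(round(stats::rlnorm(
    k, spec$island_meanlog, spec$island_sdlog)), spec$island_min), 5000L)
  hypo <- Biostrings::DNAStringSet(vapply(
    draw_len(n_hypo), make_seq, character(1),
    gc = spec$gc_background, p_cg = p_island, motifs = im))
  hyper <- Biostrings::DNAStringSet(vapply(
    draw_len(n_hyper), make_seq, character(1),
    gc = spec$gc_background, p_cg = spec$cpg_rate_background, motifs = bm))
  list(hypo = hypo, hyper = hyper)
}
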