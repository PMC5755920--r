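#' Domain caller parameters
#'
#' Defaults encode the standard domain definition: a stretch of ten or more
#' qualifying CpG dyads (methylation rate strictly below 40% for
#' hypomethylated domains, strictly above 60% for hypermethylated domains)
#' with no more than four interleaving non-qualifying or undetermined dyads.
#' The interleaving limit is a total budget per domain, not a
#' consecutive-run limit (see `interleaved_mode`).
#'
#' @param min_qualifying minimum qualifying dyads per domain (default 10).
#' @param max_interleaved maximum interleaved non-qualifying/undetermined
#'   dyads per domain (default 4).
#' @param hypo_threshold hypo-qualifying iff rate < this (default 40).
#' @param hyper_threshold hyper-qualifying iff rate > this (default 60).
#' @param min_cov coverage validity threshold (default 5).
#' @param interleaved_mode `"total"` (default) or `"run"`; `"run"` limits
#'   each consecutive run of interleaved dyads instead of their total, a
#'   sensitivity-analysis variant.
#' @return a `caller_params` list.
#' @export
caller_params <- function(min_qualifying = 10L, max_interleaved = 4L,
                          hypo_threshold = 40, hyper_threshold = 60,
                          min_cov = 5L, interleaved_mode = c("total", "run")) {
  stopifnot(min_qualifying >= 1L, max_interleaved >= 0L,
            hypo_threshold > 0, hypo_threshold < 100,
            hyper_threshold > 0, hyper_threshold < 100)
  structure(list(min_qualifying = as.integer(min_qualifying),
                 max_interleaved = as.integer(max_interleaved),
                 hypo_threshold = hypo_threshold,
                 hyper_threshold = hyper_threshold,
                 min_cov = as.integer(min_cov),
                 interleaved_mode = match.arg(interleaved_mode)),
            class = "caller_params")
}

#' Classify every genomic CpG dyad for domain calling
#'
#' Each genomic CG receives exactly one class relative to the target domain
#' kind: `qualifying` (called, rate strictly beyond the threshold),
#' `nonqualifying` (called, not qualifying; boundary rates of exactly 40 or
#' 60 are non-qualifying) or `undetermined` (no valid call after coverage
#' filtering: unsampled, unmappable or low coverage).
#'
#' @param track a coverage-filtered [methylation_track()].
#' @param cpg_sites named list of genomic CG positions per chromosome, as
#'   from [enumerate_cpg_sites()]; must be a superset of track positions.
#' @param kind `"hypo"` or `"hyper"`.
#' @param params a [caller_params()].
#' @return data.frame `chrom`, `pos`, `rate` (NA when undetermined),
#'   `class` factor, ordered by chromosome and position.
#' @export
classify_dyads <- function(track, cpg_sites, kind = c("hypo", "hyper"),
                           params = caller_params()) {
  kind <- match.arg(kind)
  pieces <- lapply(names(cpg_sites), function(ch) {
    pos <- cpg_sites[[ch]]
    tr <- track[track$chrom == ch, , drop = FALSE]
    if (nrow(tr) && !all(tr$pos %in% pos))
      stop("call at position(s) absent from the genomic CpG set on ", ch)
    rate <- rep(NA_real_, length(pos))
    rate[match(tr$pos, pos)] <- tr$rate
    data.frame(chrom = rep(ch, length(pos)), pos = pos, rate = rate)
  })
  extra <- setdiff(unique(track$chrom), names(cpg_sites))
  if (length(extra))
    stop("track chromosome(s) absent from the genomic CpG set: ",
         paste(extra, collapse = ", "))
  df <- do.call(rbind, pieces)
  qual <- if (kind == "hypo") df$rate < params$hypo_threshold
          else df$rate > params$hyper_threshold
  cls <- ifelse(is.na(df$rate), "undetermined",
                ifelse(qual, "qualifying", "nonqualifying"))
  df$class <- factor(cls, levels = c("qualifying", "nonqualifying", "undetermined"))
  df[order(df$chrom, df$pos), , drop = FALSE]
}

# Greedy segmentation of one chromosome's classified dyads.
# Domains start and end on qualifying dyads, contain >= min_qualifying of
# them and at most max_interleaved interleaved dyads; the leftmost position
# admitting a feasible domain wins and its domain is extended as far right
# as the budget allows, which reproduces the maximal-feasible-interval
# oracle with left-to-right overlap resolution.
call_domains_chrom <- function(pos, cls, rate, params) {
  n <- length(pos)
  is_q <- cls == "qualifying"
  q_idx <- which(is_q)
  out <- list()
  run_mode <- params$interleaved_mode == "run"
  qi <- 1L
  while (qi <= length(q_idx)) {
    s <- q_idx[qi]
    # scan right from s, tracking interleaved spent when ending at each
    # qualifying dyad
    spent <- 0L; run <- 0L
    best_e <- s; best_spent <- 0L; nq <- 0L
    i <- s
    while (i <= n) {
      if (is_q[i]) {
        nq <- nq + 1L
        best_e <- i; best_spent <- spent
        run <- 0L
      } else {
        run <- run + 1L
        spent <- spent + 1L
        budget <- if (run_mode) run else spent
        if (budget > params$max_interleaved) break
      }
      i <- i + 1L
    }
    if (nq >= params$min_qualifying) {
      inside <- s:best_e
      called <- inside[!is.na(rate[inside])]
      out[[length(out) + 1L]] <- data.frame(
        start = pos[s], end = pos[best_e] + 2L,
        n_qualifying = nq, n_interleaved = best_spent,
        mean_rate = if (length(called)) mean(rate[called]) else NA_real_)
      qi <- match(TRUE, q_idx > best_e)
      if (is.na(qi)) break
    } else {
      qi <- qi + 1L
    }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

#' Call methylation domains from classified dyads
#'
#' Emits maximal left-to-right segments that begin and end on qualifying
#' dyads, contain at least `min_qualifying` qualifying dyads and spend at
#' most `max_interleaved` interleaved (non-qualifying or undetermined)
#' dyads. Trailing non-qualifying dyads never count: a domain always ends on
#' its last qualifying dyad, and its half-open end coordinate is that dyad's
#' C position + 2 so the full dyad is covered.
#'
#' @param classified output of [classify_dyads()] (must be position-sorted
#'   within each chromosome).
#' @param kind `"hypo"` or `"hyper"` label stored on the output.
#' @param params a [caller_params()].
#' @return data.frame `chrom`, `start`, `end`, `kind`, `n_qualifying`,
#'   `n_interleaved`, `mean_rate` (mean over called dyads inside).
#' @export
call_domains <- function(classified, kind = c("hypo", "hyper"),
                         params = caller_params()) {
  kind <- match.arg(kind)
  pieces <- lapply(split(classified, classified$chrom), function(d) {
    if (is.unsorted(d$pos, strictly = TRUE)) stop("classified dyads not sorted")
    res <- call_domains_chrom(d$pos, as.character(d$class), d$rate, params)
    if (is.null(res)) return(NULL)
    cbind(chrom = d$chrom[1], res)
  })
  pieces <- Filter(Negate(is.null), pieces)
  if (!length(pieces))
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      kind = character(), n_qualifying = integer(),
                      n_interleaved = integer(), mean_rate = numeric()))
  out <- do.call(rbind, pieces)
  out$kind <- kind
  rownames(out) <- NULL
  out[c("chrom", "start", "end", "kind", "n_qualifying", "n_interleaved", "mean_rate")]
}

#' Call hypo- and hypermethylated domains over a genome
#'
#' Classifies every genomic CpG twice (once per kind) and calls both domain
#' kinds independently over the same positions. Overlaps between the two
#' kinds are reported, never resolved.
#'
#' @param track a coverage-filtered [methylation_track()].
#' @param genome a [Biostrings::DNAStringSet].
#' @param params a [caller_params()].
#' @return list with `hypo`, `hyper` domain tables and `overlaps`, a
#'   data.frame of overlapping hypo/hyper index pairs.
#' @export
call_all <- function(track, genome, params = caller_params()) {
  sites <- enumerate_cpg_sites(genome)
  hypo <- call_domains(classify_dyads(track, sites, "hypo", params), "hypo", params)
  hyper <- call_domains(classify_dyads(track, sites, "hyper", params), "hyper", params)
  overlaps <- data.frame(hypo_idx = integer(), hyper_idx = integer())
  if (nrow(hypo) && nrow(hyper)) {
    gr1 <- GenomicRanges::GRanges(hypo$chrom, IRanges::IRanges(hypo$start + 1L, hypo$end))
    gr2 <- GenomicRanges::GRanges(hyper$chrom, IRanges::IRanges(hyper$start + 1L, hyper$end))
    ov <- GenomicRanges::findOverlaps(gr1, gr2)
    overlaps <- data.frame(hypo_idx = S4Vectors::queryHits(ov),
                           hyper_idx = S4Vectors::subjectHits(ov))
  }
  list(hypo = hypo, hyper = hyper, overlaps = overlaps)
}

#' Summarise called domains
#'
#' Per-domain length (bp), GC content (fraction of G+C over the interval),
#' CpG density (CG dinucleotides per kb) and mean methylation rate over the
#' called dyads inside.
#'
#' @param domains a domain table from [call_domains()].
#' @param track a [methylation_track()].
#' @param genome a [Biostrings::DNAStringSet].
#' @return the domain table with `length`, `gc`, `cpg_density` and
#'   `mean_rate` columns.
#' @export
domain_summaries <- function(domains, track, genome) {
  if (!nrow(domains)) {
    domains$length <- integer(); domains$gc <- numeric()
    domains$cpg_density <- numeric()
    return(domains)
  }
  stopifnot(all(domains$chrom %in% names(genome)))
  len <- domains$end - domains$start
  gc <- numeric(nrow(domains)); dens <- numeric(nrow(domains))
  mean_rate <- numeric(nrow(domains))
  for (i in seq_len(nrow(domains))) {
    s <- Biostrings::subseq(genome[[domains$chrom[i]]],
                            domains$start[i] + 1L, domains$end[i])
    gc[i] <- sum(Biostrings::letterFrequency(s, c("G", "C"))) / len[i]
    dens[i] <- Biostrings::countPattern("CG", s) / (len[i] / 1000)
    inside <- track$chrom == domains$chrom[i] &
      track$pos >= domains$start[i] & track$pos < domains$end[i]
    mean_rate[i] <- if (any(inside)) mean(track$rate[inside]) else NA_real_
  }
  domains$length <- len
  domains$gc <- gc
  domains$cpg_density <- dens
  domains$mean_rate <- mean_rate
  domains
}
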