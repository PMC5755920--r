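#' Read fragment ectopic methylation calls
#'
#' Reads the flat TSV describing per-CpG bisulfite calls on reintegrated
#' genomic fragments: `id`, `chrom`, `start`, `end` (fragment origin,
#' 0-based half-open), `offset` (CpG position within the fragment),
#' `n_meth`, `n_unmeth`, `library` (`unmethylated` or `premethylated`).
#'
#' @param path TSV path with a header row.
#' @return a validated data.frame of fragment calls.
#' @export
read_fragment_calls <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  validate_fragment_calls(df)
}

validate_fragment_calls <- function(df) {
  need <- c("id", "chrom", "start", "end", "offset", "n_meth", "n_unmeth", "library")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("fragment calls missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(df$offset < 0 | df$offset >= df$end - df$start))
    stop("fragment CpG offset outside [0, end - start)")
  if (!all(df$library %in% c("unmethylated", "premethylated")))
    stop("library must be 'unmethylated' or 'premethylated'")
  df
}

#' Match fragment CpGs to their endogenous methylation state
#'
#' The central bookkeeping of the endogenous-vs-ectopic comparison: each
#' fragment CpG is mapped back to its genomic position (`start + offset`)
#' and paired with the endogenous methylation call at that position.
#' Fragment CpGs without a valid endogenous call are dropped and counted.
#' Each matched CpG is annotated with its endogenous domain state (`hypo`,
#' `hyper` or `other` from domain overlap), a DNase-hypersensitive-site
#' label (`inside`/`outside` at CpG level; `spanning_fragment` when the
#' whole fragment crosses a DHS boundary) and the fragment's library.
#'
#' @param frag_calls fragment call table (see [read_fragment_calls()]).
#' @param endogenous a coverage-filtered [methylation_track()].
#' @param hypo,hyper domain tables from [call_domains()] (or any
#'   [region_set()]); may be empty.
#' @param dhs a [region_set()] of DNase-hypersensitive sites, or NULL.
#' @param genome optional [Biostrings::DNAStringSet] for bounds checking.
#' @return a `matched_cpg` data.frame: `fragment_id`, `chrom`, `pos`,
#'   `endogenous_rate`, `ectopic_rate`, `ect_n_meth`, `ect_n_unmeth`,
#'   `origin_state`, `dhs`, `library`; attributes `n_unmatched` (fragment
#'   CpGs without an endogenous call) and `frac_fragments_contained`
#'   (fraction of fragments not crossing a DHS boundary).
#' @export
match_cpgs <- function(frag_calls, endogenous, hypo = NULL, hyper = NULL,
                       dhs = NULL, genome = NULL) {
  frag_calls <- validate_fragment_calls(frag_calls)
  if (!is.null(genome)) {
    chrlen <- stats::setNames(Biostrings::width(genome), names(genome))
    if (!all(frag_calls$chrom %in% names(genome)) ||
        any(frag_calls$start < 0 | frag_calls$end > chrlen[frag_calls$chrom]))
      stop("fragment outside genome bounds")
  }
  pos <- frag_calls$start + frag_calls$offset
  key <- paste(frag_calls$chrom, pos)
  ekey <- paste(endogenous$chrom, endogenous$pos)
  hit <- match(key, ekey)
  n_unmatched <- sum(is.na(hit))
  keep <- !is.na(hit)
  fc <- frag_calls[keep, , drop = FALSE]
  pos <- pos[keep]; hit <- hit[keep]
  cov <- fc$n_meth + fc$n_unmeth
  out <- data.frame(fragment_id = fc$id, chrom = fc$chrom, pos = pos,
                    endogenous_rate = endogenous$rate[hit],
                    ectopic_rate = ifelse(cov > 0, 100 * fc$n_meth / pmax(cov, 1), NA_real_),
                    ect_n_meth = fc$n_meth, ect_n_unmeth = fc$n_unmeth,
                    library = fc$library, stringsAsFactors = FALSE)

  out$origin_state <- rep("other", nrow(out))
  label_state <- function(state, regions) {
    if (is.null(regions) || !nrow(regions)) return()
    gr <- GenomicRanges::GRanges(regions$chrom,
                                 IRanges::IRanges(regions$start + 1L, regions$end))
    cg <- GenomicRanges::GRanges(out$chrom, IRanges::IRanges(out$pos + 1L, out$pos + 2L))
    ov <- GenomicRanges::findOverlaps(cg, gr)
    out$origin_state[unique(S4Vectors::queryHits(ov))] <<- state
  }
  label_state("hyper", hyper)
  label_state("hypo", hypo)  # hypo wins on (reported, unresolved) overlaps

  out$dhs <- rep(NA_character_, nrow(out))
  frac_contained <- NA_real_
  if (!is.null(dhs) && nrow(dhs)) {
    dgr <- GenomicRanges::GRanges(dhs$chrom, IRanges::IRanges(dhs$start + 1L, dhs$end))
    frags <- unique(fc[c("id", "chrom", "start", "end")])
    fgr <- GenomicRanges::GRanges(frags$chrom,
                                  IRanges::IRanges(frags$start + 1L, frags$end))
    ov <- GenomicRanges::findOverlaps(fgr, dgr)
    spanning_ids <- character()
    if (length(ov)) {
      q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
      contained <- IRanges::start(fgr)[q] >= IRanges::start(dgr)[s] &
        IRanges::end(fgr)[q] <= IRanges::end(dgr)[s]
      spanning_ids <- frags$id[unique(q[!contained])]
    }
    frac_contained <- 1 - length(spanning_ids) / nrow(frags)
    cg <- GenomicRanges::GRanges(out$chrom, IRanges::IRanges(out$pos + 1L, out$pos + 2L))
    inside <- rep(FALSE, nrow(out))
    cov_ov <- GenomicRanges::findOverlaps(cg, dgr, type = "within")
    inside[unique(S4Vectors::queryHits(cov_ov))] <- TRUE
    out$dhs <- ifelse(out$fragment_id %in% spanning_ids, "spanning_fragment",
                      ifelse(inside, "inside", "outside"))
  }
  class(out) <- c("matched_cpg", "data.frame")
  attr(out, "n_unmatched") <- n_unmatched
  attr(out, "frac_fragments_contained") <- frac_contained
  out
}

#' Pool matched CpGs across fragments
#'
#' Sums ectopic counts per genomic CpG and library across all integration
#' events (the pooled-embryo sequencing design), recomputing the ectopic
#' rate from the summed counts.
#'
#' @param matched a `matched_cpg` table.
#' @return one row per (chrom, pos, library) with pooled counts and rates.
#' @export
pool_matched_cpgs <- function(matched) {
  key <- paste(matched$chrom, matched$pos, matched$library, sep = "\r")
  agg <- function(x, f) as.vector(tapply(x, key, f))
  first <- !duplicated(key)
  ord <- match(sort(unique(key)), key[first])
  base <- matched[first, , drop = FALSE][ord, , drop = FALSE]
  nm <- agg(matched$ect_n_meth, sum)
  nu <- agg(matched$ect_n_unmeth, sum)
  out <- data.frame(chrom = base$chrom, pos = base$pos,
                    endogenous_rate = base$endogenous_rate,
                    ect_n_meth = nm, ect_n_unmeth = nu,
                    ectopic_rate = ifelse(nm + nu > 0, 100 * nm / pmax(nm + nu, 1), NA_real_),
                    origin_state = base$origin_state, dhs = base$dhs,
                    library = base$library, stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos, out$library), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("matched_cpg", "data.frame")
  out
}

#' Rank correlations between endogenous and ectopic methylation
#'
#' Spearman's rho and Kendall's tau-b (tie-corrected — ectopic rates are
#' heavily tied at 0 and 100) over (endogenous, ectopic) rate pairs,
#' optionally within a stratum.
#'
#' @param matched a `matched_cpg` table.
#' @param origin_state,dhs,library optional stratum filters (values to keep).
#' @param stratum label stored on the report.
#' @return data.frame `stratum`, `spearman_rho`, `kendall_tau`, `n`,
#'   `degenerate` (TRUE when a constant vector made the coefficients
#'   undefined).
#' @export
correlate <- function(matched, origin_state = NULL, dhs = NULL, library = NULL,
                      stratum = "all") {
  m <- matched
  if (!is.null(origin_state)) m <- m[m$origin_state %in% origin_state, , drop = FALSE]
  if (!is.null(dhs)) m <- m[!is.na(m$dhs) & m$dhs %in% dhs, , drop = FALSE]
  if (!is.null(library)) m <- m[m$library %in% library, , drop = FALSE]
  m <- m[!is.na(m$endogenous_rate) & !is.na(m$ectopic_rate), , drop = FALSE]
  if (nrow(m) < 2) stop("fewer than 2 pairs after filtering")
  degenerate <- stats::sd(m$endogenous_rate) == 0 || stats::sd(m$ectopic_rate) == 0
  rho <- tau <- NA_real_
  if (!degenerate) {
    rho <- stats::cor(m$endogenous_rate, m$ectopic_rate, method = "spearman")
    tau <- stats::cor(m$endogenous_rate, m$ectopic_rate, method = "kendall")
  }
  data.frame(stratum = stratum, spearman_rho = rho, kendall_tau = tau,
             n = nrow(m), degenerate = degenerate)
}

#' Histogram of methylation rates in 1% bins
#'
#' Bins `[0,1), [1,2), ..., [99,100]`; a rate of exactly 100 falls in the
#' last bin. Counts always sum to the number of rates.
#'
#' @param rates percentages in \[0,100\].
#' @param bin_width bin width in percent (default 1).
#' @return data.frame `bin_start`, `bin_end`, `count`.
#' @export
rate_histogram <- function(rates, bin_width = 1) {
  rates <- rates[!is.na(rates)]
  if (any(rates < 0 | rates > 100)) stop("rate outside [0,100]")
  nb <- ceiling(100 / bin_width)
  idx <- pmin(floor(rates / bin_width), nb - 1)
  counts <- tabulate(idx + 1L, nbins = nb)
  data.frame(bin_start = (seq_len(nb) - 1L) * bin_width,
             bin_end = pmin(seq_len(nb) * bin_width, 100),
             count = counts)
}

#' Per-fragment summaries of matched CpGs
#'
#' @param matched a `matched_cpg` table.
#' @param frag_calls optional fragment call table supplying fragment
#'   coordinates, for `length` and `cpg_density`.
#' @return one row per fragment: `fragment_id`, `library`, `n_cpg`,
#'   `length`, `cpg_density` (matched CpGs per kb), `mean_endogenous`,
#'   `mean_ectopic`.
#' @export
fragment_summaries <- function(matched, frag_calls = NULL) {
  sp <- split(seq_len(nrow(matched)), matched$fragment_id)
  rows <- lapply(sp, function(i) {
    m <- matched[i, , drop = FALSE]
    len <- NA_integer_
    if (!is.null(frag_calls)) {
      f <- frag_calls[match(m$fragment_id[1], frag_calls$id), ]
      len <- f$end - f$start
    }
    data.frame(fragment_id = m$fragment_id[1], library = m$library[1],
               n_cpg = nrow(m), length = len,
               cpg_density = if (is.na(len)) NA_real_ else nrow(m) / (len / 1000),
               mean_endogenous = mean(m$endogenous_rate, na.rm = TRUE),
               mean_ectopic = mean(m$ectopic_rate, na.rm = TRUE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Stratify matched CpGs by fragment-level endogenous state and library
#'
#' A fragment is endogenously hypomethylated when its mean endogenous CpG
#' methylation rate is below 40%, hypermethylated above 60%; intermediate
#' fragments are excluded and counted. Crossing with the two libraries
#' yields the four analysis panels.
#'
#' @param matched a `matched_cpg` table.
#' @param hypo_threshold,hyper_threshold fragment-mean cutoffs (40/60).
#' @return list with `matched` (input rows plus `fragment_state` and
#'   `stratum`, excluded fragments dropped) and `n_excluded_fragments`.
#' @export
fragment_state_stratify <- function(matched, hypo_threshold = 40,
                                    hyper_threshold = 60) {
  means <- tapply(matched$endogenous_rate, matched$fragment_id, mean, na.rm = TRUE)
  state <- ifelse(means < hypo_threshold, "hypo",
                  ifelse(means > hyper_threshold, "hyper", "excluded"))
  fs <- as.vector(state[as.character(matched$fragment_id)])
  keep <- fs != "excluded"
  out <- matched[keep, , drop = FALSE]
  out$fragment_state <- fs[keep]
  out$stratum <- paste(out$fragment_state, out$library, sep = ".")
  list(matched = out, n_excluded_fragments = sum(state == "excluded"))
}

#' Fragment-feature correlations
#'
#' Correlates each fragment's overall (mean) ectopic methylation rate with
#' its length and with its CpG density, per stratum.
#'
#' @param frag_summ output of [fragment_summaries()], optionally with a
#'   `stratum` column.
#' @return data.frame with one row per stratum x feature: Spearman rho,
#'   Kendall tau-b, `n`, `low_n` flag (n < 10).
#' @export
fragment_feature_correlation <- function(frag_summ) {
  if (nrow(frag_summ) < 2) stop("need at least 2 fragments")
  strata <- if ("stratum" %in% names(frag_summ)) split(frag_summ, frag_summ$stratum)
            else list(all = frag_summ)
  rows <- list()
  for (nm in names(strata)) {
    d <- strata[[nm]]
    for (feat in c("length", "cpg_density")) {
      if (nrow(d) < 2 || all(is.na(d[[feat]]))) next
      degenerate <- stats::sd(d[[feat]], na.rm = TRUE) == 0 ||
        stats::sd(d$mean_ectopic, na.rm = TRUE) == 0
      rows[[length(rows) + 1L]] <- data.frame(
        stratum = nm, feature = feat,
        spearman_rho = if (degenerate) NA_real_ else
          stats::cor(d[[feat]], d$mean_ectopic, method = "spearman",
                     use = "complete.obs"),
        kendall_tau = if (degenerate) NA_real_ else
          stats::cor(d[[feat]], d$mean_ectopic, method = "kendall",
                     use = "complete.obs"),
        n = nrow(d), low_n = nrow(d) < 10)
    }
  }
  do.call(rbind, rows)
}
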