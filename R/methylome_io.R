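#' Construct a per-CpG methylation track
#'
#' A methylation track is the package's container for per-CpG bisulfite
#' methylation evidence: one row per CpG dyad, addressed by the 0-based
#' position of the C of the CG dinucleotide on the plus strand. Counts are
#' authoritative: whenever a dyad has coverage, its rate is recomputed as
#' `100 * n_meth / (n_meth + n_unmeth)`, overriding any (possibly rounded)
#' rate supplied by the caller.
#'
#' @param chrom character vector of chromosome names.
#' @param pos integer vector, 0-based position of the plus-strand C.
#' @param n_meth,n_unmeth non-negative integer counts of methylated and
#'   unmethylated calls.
#' @param rate optional percent in \[0,100\]; checked against the counts
#'   (within 0.5 points, input files may round) and then replaced by the
#'   exact count-derived value. Required only for zero-coverage rows.
#' @return a `methylation_track` data.frame with columns `chrom`, `pos`,
#'   `n_meth`, `n_unmeth`, `rate`, sorted by chromosome then position.
#' @export
methylation_track <- function(chrom, pos, n_meth, n_unmeth, rate = NULL) {
  n <- length(pos)
  if (length(chrom) == 1L && n > 1L) chrom <- rep(chrom, n)
  stopifnot(length(chrom) == n, length(n_meth) == n, length(n_unmeth) == n)
  if (any(n_meth < 0) || any(n_unmeth < 0))
    stop("methylation counts must be non-negative")
  cov <- n_meth + n_unmeth
  exact <- ifelse(cov > 0, 100 * n_meth / pmax(cov, 1L), NA_real_)
  if (!is.null(rate)) {
    if (any(rate < 0 | rate > 100, na.rm = TRUE))
      stop("methylation rate outside [0,100]")
    bad <- which(cov > 0 & abs(rate - exact) > 0.5)
    if (length(bad))
      stop("rate inconsistent with counts at row(s) ", paste(utils::head(bad, 5), collapse = ", "))
    exact[cov == 0] <- rate[cov == 0]
  } else {
    exact[cov == 0] <- 0
  }
  df <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                   n_meth = as.integer(n_meth), n_unmeth = as.integer(n_unmeth),
                   rate = exact, stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  if (anyDuplicated(df[c("chrom", "pos")]))
    stop("duplicate (chrom, pos) in methylation track")
  rownames(df) <- NULL
  class(df) <- c("methylation_track", "data.frame")
  df
}

#' Read a per-CpG methylation call table
#'
#' Reads the six-column bedGraph dialect written by common methylation
#' extractors: `chrom start end rate n_meth n_unmeth`, whitespace-separated,
#' with `start` the 0-based position of the plus-strand C. `track`,
#' `browser` and `#` header lines are skipped.
#'
#' @param path path to the table.
#' @param dialect currently only `"bedgraph6"`.
#' @return a [methylation_track()].
#' @export
read_methylation_table <- function(path, dialect = c("bedgraph6")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  is_header <- grepl("^(track|browser|#)", lines) | !nzchar(trimws(lines))
  data_idx <- which(!is_header)
  if (!length(data_idx))
    return(methylation_track(character(), integer(), integer(), integer()))
  fields <- strsplit(trimws(lines[data_idx]), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf != 6))
    stop("malformed row at line ", data_idx[which(nf != 6)[1]],
         ": expected 6 fields, got ", nf[which(nf != 6)[1]])
  m <- matrix(unlist(fields), ncol = 6, byrow = TRUE)
  num <- suppressWarnings(apply(m[, 2:6, drop = FALSE], 2, as.numeric))
  num <- matrix(num, ncol = 5)
  if (anyNA(num))
    stop("malformed row at line ", data_idx[which(rowSums(is.na(num)) > 0)[1]],
         ": non-numeric field")
  if (any(num[, 3] < 0 | num[, 3] > 100))
    stop("rate outside [0,100] at line ", data_idx[which(num[, 3] < 0 | num[, 3] > 100)[1]])
  methylation_track(chrom = m[, 1], pos = num[, 1],
                    n_meth = num[, 4], n_unmeth = num[, 5], rate = num[, 3])
}

#' Write a methylation track in the bedGraph dialect
#' @param track a [methylation_track()].
#' @param path output path.
#' @export
write_methylation_table <- function(track, path) {
  df <- data.frame(track$chrom, track$pos, track$pos + 2L,
                   formatC(track$rate, format = "fg", digits = 10),
                   track$n_meth, track$n_unmeth)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Merge plus- and minus-strand calls of each CpG dyad
#'
#' Some extraction dialects report the two strands of a CpG dyad separately:
#' the plus-strand C at `pos` and the minus-strand C (a plus-strand G) at
#' `pos + 1`. This sums both into a single call addressed at `pos`, the
#' field's convention for symmetric CpG methylation, and recomputes the rate
#' from the summed counts. Calls whose genomic context is not part of a CG
#' dinucleotide are preserved unmerged and reported via the
#' `"unmerged_warnings"` attribute.
#'
#' @param track a [methylation_track()].
#' @param genome a [Biostrings::DNAStringSet] with names matching `chrom`.
#' @return a merged `methylation_track`; total counts over CG-context calls
#'   are conserved.
#' @export
merge_dyad_strands <- function(track, genome) {
  if (!nrow(track)) return(track)
  stopifnot(all(track$chrom %in% names(genome)))
  # vectorised context lookup: the letter at pos, pos+1 and pos-1
  letter <- function(chrom, pos) {
    out <- rep(NA_character_, length(pos))
    for (ch in unique(chrom)) {
      i <- which(chrom == ch)
      s <- genome[[ch]]
      len <- length(s)
      ok <- pos[i] >= 0L & pos[i] < len
      if (any(ok)) {
        v <- Biostrings::extractAt(s, IRanges::IRanges(pos[i[ok]] + 1L, width = 1L))
        out[i[ok]] <- as.character(v)
      }
    }
    out
  }
  here <- letter(track$chrom, track$pos)
  nxt  <- letter(track$chrom, track$pos + 1L)
  prv  <- letter(track$chrom, track$pos - 1L)

  anchor <- rep(NA_integer_, nrow(track))
  plusC  <- !is.na(here) & here == "C" & !is.na(nxt) & nxt == "G"
  minusC <- !plusC & !is.na(here) & here == "G" & !is.na(prv) & prv == "C"
  anchor[plusC]  <- track$pos[plusC]
  anchor[minusC] <- track$pos[minusC] - 1L
  noncg <- is.na(anchor)
  anchor[noncg] <- track$pos[noncg]  # preserved as-is

  key <- paste(track$chrom, anchor)
  nm <- tapply(track$n_meth, key, sum)
  nu <- tapply(track$n_unmeth, key, sum)
  kk <- names(nm)
  sp <- regmatches(kk, regexpr(" ", kk), invert = TRUE)
  chrom <- vapply(sp, `[`, "", 1L)
  pos <- as.integer(vapply(sp, `[`, "", 2L))
  out <- methylation_track(chrom, pos, as.integer(nm), as.integer(nu))
  attr(out, "unmerged_warnings") <-
    data.frame(chrom = track$chrom[noncg], pos = track$pos[noncg])
  if (any(noncg))
    warning(sum(noncg), " call(s) at non-CG genomic positions left unmerged")
  out
}

#' Filter a methylation track by minimum coverage
#'
#' Dyads with fewer than `min_cov` total calls are dropped; genome CpGs that
#' disappear here become "undetermined" for domain calling. The default of
#' 5x is the validity threshold used throughout the pipeline.
#'
#' @param track a [methylation_track()].
#' @param min_cov minimum coverage (`n_meth + n_unmeth`), default 5.
#' @return the filtered track, order preserved. Idempotent.
#' @export
filter_coverage <- function(track, min_cov = 5L) {
  stopifnot(min_cov >= 1L)
  keep <- (track$n_meth + track$n_unmeth) >= min_cov
  out <- track[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("methylation_track", "data.frame")
  out
}

#' Enumerate genomic CpG sites
#'
#' Returns, per chromosome, every 0-based position p with `genome[p] == "C"`
#' and `genome[p+1] == "G"`. CG occurrences cannot overlap, so the scan is
#' exhaustive by construction.
#'
#' @param genome a [Biostrings::DNAStringSet].
#' @return named list of strictly increasing integer vectors.
#' @export
enumerate_cpg_sites <- function(genome) {
  out <- lapply(seq_along(genome), function(i) {
    hits <- Biostrings::matchPattern("CG", genome[[i]])
    as.integer(BiocGenerics::start(hits)) - 1L
  })
  names(out) <- names(genome)
  out
}

#' Read and write BED region sets
#'
#' Regions are 0-based half-open intervals with optional `name` and `score`
#' columns (BED3/BED4/BED5). `read_regions(write_regions(x)) == x`.
#' Chromosome names are matched by exact string equality throughout the
#' package; no alias table is applied.
#'
#' @param path file path.
#' @return a `region_set` data.frame with columns `chrom`, `start`, `end`
#'   and, when present, `name` and `score`; sorted within chromosome.
#' @export
read_regions <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^(track|browser|#)", lines)]
  if (!length(lines)) return(region_set(character(), integer(), integer()))
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- unique(lengths(fields))
  if (length(nf) != 1 || nf[1] < 3)
    stop("BED rows must have a constant column count >= 3")
  m <- matrix(unlist(fields), ncol = nf[1], byrow = TRUE)
  region_set(chrom = m[, 1], start = as.integer(m[, 2]), end = as.integer(m[, 3]),
             name = if (nf >= 4) m[, 4] else NULL,
             score = if (nf >= 5) as.numeric(m[, 5]) else NULL)
}

#' @rdname read_regions
#' @param chrom,start,end,name,score region fields; `start < end` required.
#' @export
region_set <- function(chrom, start, end, name = NULL, score = NULL) {
  if (any(start >= end)) stop("region with start >= end")
  df <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                   end = as.integer(end), stringsAsFactors = FALSE)
  if (!is.null(name)) df$name <- as.character(name)
  if (!is.null(score)) df$score <- score
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("region_set", "data.frame")
  df
}

#' @rdname read_regions
#' @param regions a `region_set`.
#' @export
write_regions <- function(regions, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score"), names(regions))
  utils::write.table(regions[cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname read_regions
#' @param domains a domain table from [call_domains()]; written as BED5 with
#'   `name` = HypoMD/HyperMD and `score` = number of qualifying dyads.
#' @export
write_domains <- function(domains, path) {
  name <- ifelse(domains$kind == "hypo", "HypoMD", "HyperMD")
  write_regions(region_set(domains$chrom, domains$start, domains$end,
                           name = name, score = domains$n_qualifying), path)
}

#' Per-CpG methylation rates from a clone-by-site matrix
#'
#' Summarises bisulfite-PCR clone sequencing panels: rows are clones,
#' columns are CpG sites, entries are 1 (methylated), 0 (unmethylated) or
#' NA (missing/unreadable). The per-site rate ignores missing entries; a
#' site with no informative clone is flagged undetermined.
#'
#' @param mat numeric matrix of 0/1/NA, clones x sites. Character matrices
#'   with "M"/"U" entries are accepted.
#' @return data.frame with `site`, `n_meth`, `n_unmeth`, `rate` (percent,
#'   NA when undetermined) and `undetermined`.
#' @export
clone_matrix_rate <- function(mat) {
  if (!length(mat)) stop("empty clone matrix")
  if (is.character(mat)) {
    m <- matrix(NA_real_, nrow(mat), ncol(mat), dimnames = dimnames(mat))
    m[mat %in% c("M", "m", "1")] <- 1
    m[mat %in% c("U", "u", "0")] <- 0
    mat <- m
  }
  n_meth <- colSums(mat == 1, na.rm = TRUE)
  n_unmeth <- colSums(mat == 0, na.rm = TRUE)
  info <- n_meth + n_unmeth
  data.frame(site = if (is.null(colnames(mat))) seq_len(ncol(mat)) else colnames(mat),
             n_meth = n_meth, n_unmeth = n_unmeth,
             rate = ifelse(info > 0, 100 * n_meth / pmax(info, 1), NA_real_),
             undetermined = info == 0, row.names = NULL)
}

#' Read a genome FASTA
#' @param path FASTA path.
#' @return an uppercase [Biostrings::DNAStringSet] named by the first word
#'   of each header.
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  Biostrings::DNAStringSet(toupper(g))
}

#' Write a genome FASTA
#' @param genome a [Biostrings::DNAStringSet].
#' @param path output path.
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}
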