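#' Read a Sanger peak-height table
#'
#' A peak table is the per-position called peak height in each of the four
#' base channels of a Sanger trace: columns `position`, `A`, `C`, `G`, `T`
#' (non-negative reals). Methylation sites are annotated on the
#' bisulfite-converted amplicon frame; PAM third-base sites on the
#' unconverted frame — the two are separate tables.
#'
#' @param path TSV with a header row.
#' @return a validated `peak_table` data.frame.
#' @export
read_peak_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  peak_table(df)
}

#' @rdname read_peak_table
#' @param df data.frame with `position`, `A`, `C`, `G`, `T`.
#' @export
peak_table <- function(df) {
  need <- c("position", "A", "C", "G", "T")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("peak table missing column(s): ", paste(miss, collapse = ", "))
  if (any(df$A < 0 | df$C < 0 | df$G < 0 | df$T < 0))
    stop("peak heights must be non-negative")
  if (anyDuplicated(df$position)) stop("duplicate positions in peak table")
  df <- df[order(df$position), need, drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("peak_table", "data.frame")
  df
}

#' Methylation rate from bisulfite-trace peak heights
#'
#' On a bisulfite-converted amplicon a methylated cytosine reads C and an
#' unmethylated one reads T, so the methylation rate at a CpG is
#' `C / (C + T) * 100` from the two channel heights. Scale-invariant in the
#' heights.
#'
#' @param height_C,height_T non-negative peak heights (vectorized).
#' @return percent in \[0,100\].
#' @export
methylation_rate <- function(height_C, height_T) {
  if (any(height_C < 0 | height_T < 0)) stop("peak heights must be non-negative")
  tot <- height_C + height_T
  if (any(tot == 0)) stop("undetermined site: C + T peak heights are both zero")
  100 * height_C / tot
}

#' Editing rate from PAM third-base peak heights
#'
#' Editing replaces the native PAM (5'-NGG-3') with a mutated one
#' (5'-NGC-3'), so at each annotated PAM third base the edited-allele
#' fraction is `edited / (edited + native) * 100` from the corresponding
#' channel heights (C vs G by default). The locus editing rate aggregates
#' the per-site fractions by unweighted mean (or median).
#'
#' @param trace a `peak_table` on the unconverted amplicon frame.
#' @param pam_sites positions (matching `trace$position`) of PAM third bases.
#' @param edited_base,native_base channels to compare (defaults C and G).
#' @param aggregate `"mean"` (default) or `"median"`.
#' @return list with `per_site` (data.frame `position`, `edited_fraction`),
#'   `locus_rate` (percent) and `n_skipped` zero-signal sites.
#' @export
editing_rate <- function(trace, pam_sites, edited_base = "C", native_base = "G",
                         aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  if (!length(pam_sites)) stop("at least one PAM site required")
  idx <- match(pam_sites, trace$position)
  if (anyNA(idx)) stop("PAM site(s) absent from peak table: ",
                       paste(pam_sites[is.na(idx)], collapse = ", "))
  h_ed <- trace[[edited_base]][idx]
  h_na <- trace[[native_base]][idx]
  tot <- h_ed + h_na
  skip <- tot == 0
  if (any(skip))
    warning(sum(skip), " PAM site(s) with zero signal skipped")
  if (all(skip)) stop("all PAM sites have zero signal")
  frac <- 100 * h_ed[!skip] / tot[!skip]
  list(per_site = data.frame(position = pam_sites[!skip], edited_fraction = frac),
       locus_rate = if (aggregate == "mean") mean(frac) else stats::median(frac),
       n_skipped = sum(skip))
}

#' Editing-normalized methylation rate
#'
#' At partial editing only the edited alleles carry the installed
#' methylation, so the raw trace methylation rate understates the rate on
#' edited alleles. Normalizing divides the methylation rate by the locus
#' editing rate; at 100% editing this is the identity. Quotients above
#' 100% (possible at low editing) are capped at 100 and flagged.
#'
#' @param rate_percent methylation rate(s) in percent.
#' @param editing_percent locus editing rate in percent, > 0.
#' @param cap cap at 100% (default TRUE).
#' @return numeric vector of normalized percentages with a logical
#'   `"capped"` attribute marking entries whose raw quotient exceeded 100.
#' @export
normalize_methylation <- function(rate_percent, editing_percent, cap = TRUE) {
  if (any(editing_percent <= 0)) stop("editing rate must be > 0")
  out <- 100 * (rate_percent / 100) / (editing_percent / 100)
  over <- out > 100
  if (cap) out[over] <- 100
  attr(out, "capped") <- over
  out
}

#' Quantify methylation and editing at an edited locus
#'
#' Applies [methylation_rate()] at every annotated CpG of the bisulfite
#' trace, [editing_rate()] at the annotated PAM sites of the native trace,
#' and [normalize_methylation()] per CpG. When no PAM annotation is
#' supplied, methylation rates are still computed but normalization is
#' refused (normalized rates are NA).
#'
#' @param meth_trace `peak_table` on the bisulfite frame.
#' @param cpg_sites positions of CpG cytosines in `meth_trace`.
#' @param pam_trace `peak_table` on the unconverted frame (defaults to
#'   `meth_trace` when the locus was read from a single table).
#' @param pam_sites positions of PAM third bases in `pam_trace`, or NULL.
#' @param aggregate locus editing aggregation, `"mean"` or `"median"`.
#' @return a `trace_quant` list: `per_cpg` (data.frame `position`, `rate`,
#'   `normalized_rate`, `capped`), `editing` (as [editing_rate()], or NULL),
#'   `undetermined_sites` (CpGs with zero C+T signal, reported not scored).
#' @export
quantify_locus <- function(meth_trace, cpg_sites, pam_trace = meth_trace,
                           pam_sites = NULL, aggregate = "mean") {
  idx <- match(cpg_sites, meth_trace$position)
  if (anyNA(idx)) stop("CpG site(s) absent from peak table: ",
                       paste(cpg_sites[is.na(idx)], collapse = ", "))
  hC <- meth_trace$C[idx]; hT <- meth_trace$T[idx]
  det <- hC + hT > 0
  rate <- rep(NA_real_, length(idx))
  rate[det] <- methylation_rate(hC[det], hT[det])
  editing <- NULL
  norm <- rep(NA_real_, length(idx))
  capped <- rep(NA, length(idx))
  if (!is.null(pam_sites) && length(pam_sites)) {
    editing <- editing_rate(pam_trace, pam_sites, aggregate = aggregate)
    nv <- normalize_methylation(rate[det], editing$locus_rate)
    norm[det] <- nv
    capped[det] <- attr(nv, "capped")
  }
  structure(list(per_cpg = data.frame(position = cpg_sites, rate = rate,
                                      normalized_rate = norm, capped = capped),
                 editing = editing,
                 undetermined_sites = cpg_sites[!det]),
            class = "trace_quant")
}
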