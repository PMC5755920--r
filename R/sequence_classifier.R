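#' k-mer spectrum featurizer configuration
#'
#' The spectrum representation counts every length-`k` window of a
#' sequence; two sequences are similar when their k-mer count vectors are.
#' Defaults follow the standard domain-classification setup: `k = 6`,
#' reverse-complement collapsing (a domain and its reverse strand get the
#' same vector), and L2 normalization of the count vector.
#'
#' @param k word length, 1..8 (default 6).
#' @param collapse_reverse_complement pool each k-mer with its reverse
#'   complement into one canonical feature (default TRUE).
#' @param mask_cpg replace every CG dinucleotide by NN before counting,
#'   removing CpG-density information from the features (default FALSE).
#' @param normalization `"l2"` (default) or `"none"`.
#' @return a `featurizer_config` list.
#' @export
featurizer_config <- function(k = 6L, collapse_reverse_complement = TRUE,
                              mask_cpg = FALSE, normalization = c("l2", "none")) {
  stopifnot(k >= 1L, k <= 8L)
  structure(list(k = as.integer(k),
                 collapse_reverse_complement = isTRUE(collapse_reverse_complement),
                 mask_cpg = isTRUE(mask_cpg),
                 normalization = match.arg(normalization)),
            class = "featurizer_config")
}

#' Mask CpG dinucleotides
#'
#' Replaces every CG occurrence by NN, preserving length. Used to control
#' for CpG density as a confounder when asking whether non-CpG sequence
#' features distinguish domain classes.
#'
#' @param sequences character vector or [Biostrings::DNAStringSet] over
#'   A/C/G/T/N.
#' @return object of the same type with every CG replaced by NN.
#' @export
mask_cpg <- function(sequences) {
  was_xss <- methods::is(sequences, "XStringSet")
  s <- gsub("CG", "NN", as.character(sequences), fixed = TRUE)
  if (was_xss) Biostrings::DNAStringSet(s) else s
}

canonical_kmers <- function(k) {
  all <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), k)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(all)))
  pmin(all, rc)
}

#' k-mer spectrum vectors for a set of sequences
#'
#' Counts every length-`k` window consisting solely of A/C/G/T (windows
#' containing N contribute nothing), optionally pools reverse-complement
#' k-mer pairs into one canonical feature, and optionally L2-normalizes
#' each row. An N-free sequence of length L yields `L - k + 1` total counts
#' before collapsing.
#'
#' @param sequences character vector or [Biostrings::DNAStringSet].
#' @param config a [featurizer_config()].
#' @return numeric matrix, one row per sequence, columns named by
#'   (canonical) k-mer.
#' @export
featurize <- function(sequences, config = featurizer_config()) {
  seqs <- if (methods::is(sequences, "XStringSet")) sequences
          else Biostrings::DNAStringSet(as.character(sequences))
  if (config$mask_cpg) seqs <- mask_cpg(seqs)
  X <- Biostrings::oligonucleotideFrequency(seqs, width = config$k)
  X <- matrix(as.numeric(X), nrow = length(seqs), dimnames = dimnames(X))
  if (config$collapse_reverse_complement) {
    canon <- canonical_kmers(config$k)
    X <- t(rowsum(t(X), group = canon))
    X <- X[, sort(colnames(X)), drop = FALSE]
  }
  if (config$normalization == "l2") {
    nrm <- sqrt(rowSums(X^2))
    nz <- nrm > 0
    X[nz, ] <- X[nz, , drop = FALSE] / nrm[nz]
  }
  X
}

#' Train a class-weighted k-mer spectrum linear SVM
#'
#' Fits a soft-margin linear SVM on spectrum vectors with per-class sample
#' costs: positives get cost `C * class_weight`, negatives `C`. With the
#' default `class_weight = "auto"` the positive weight is the class-size
#' ratio n_neg / n_pos, offsetting class imbalance (class sizes of
#' 231516 HyperMDs vs 18435 HypoMDs give 12.56). The decision
#' value of a sequence is `<weights, x> + bias`.
#'
#' @param positives,negatives sequences of the two classes (character or
#'   [Biostrings::DNAStringSet]); both non-empty.
#' @param config a [featurizer_config()].
#' @param class_weight `"auto"` or a positive number.
#' @param C soft-margin constant (default 1).
#' @param fit_bias include an intercept (default TRUE).
#' @param seed seed for the optimizer's sample-visitation order.
#' @return a `spectrum_model` with elements `weights` (named by k-mer),
#'   `bias`, `class_weight`, `C`, `config`.
#' @export
train_spectrum_svm <- function(positives, negatives, config = featurizer_config(),
                               class_weight = "auto", C = 1, fit_bias = TRUE,
                               seed = 1L) {
  if (!length(positives) || !length(negatives))
    stop("both classes must be non-empty")
  w_pos <- if (identical(class_weight, "auto"))
    default_class_weight(length(positives), length(negatives)) else class_weight
  stopifnot(w_pos > 0)
  Xp <- featurize(positives, config)
  Xn <- featurize(negatives, config)
  if (all(rowSums(abs(Xp)) == 0) || all(rowSums(abs(Xn)) == 0))
    stop("a class has no usable (non-empty) spectrum vectors")
  X <- rbind(Xp, Xn)
  y <- c(rep(1, nrow(Xp)), rep(-1, nrow(Xn)))
  cost <- c(rep(C * w_pos, nrow(Xp)), rep(C, nrow(Xn)))
  if (fit_bias) X <- cbind(X, `(bias)` = 1)
  fit <- dcd_svm(X, y, cost, max_iter = 1000L, eps = 1e-3, seed = as.integer(seed))
  w <- fit$w
  bias <- if (fit_bias) w[length(w)] else 0
  if (fit_bias) w <- w[-length(w)]
  names(w) <- colnames(X)[seq_along(w)]
  structure(list(weights = w, bias = bias, class_weight = w_pos, C = C,
                 config = config, iterations = fit$iterations),
            class = "spectrum_model")
}

#' Default positive-class weight from class sizes
#' @param n_pos,n_neg class sizes.
#' @return `n_neg / n_pos`.
#' @export
default_class_weight <- function(n_pos, n_neg) n_neg / n_pos

#' Decision values of a spectrum model
#' @param model a `spectrum_model`.
#' @param sequences sequences to score.
#' @return numeric decision values; positive predicts the positive class.
#' @export
decision_values <- function(model, sequences) {
  X <- featurize(sequences, model$config)
  drop(X[, names(model$weights), drop = FALSE] %*% model$weights) + model$bias
}

#' Area under the precision-recall curve (average precision)
#'
#' Average precision with step interpolation: precision at each distinct
#' decision-value threshold, summed over recall increments. Tied decision
#' values are grouped at one threshold. For a random scorer the expectation
#' equals the positive-class prevalence, see [random_baseline()].
#'
#' @param decision_values numeric scores, higher = more positive.
#' @param labels logical or 0/1; must contain both classes.
#' @return AUPRC in \[0,1\].
#' @export
auprc <- function(decision_values, labels) {
  labels <- as.logical(labels)
  if (!any(labels) || all(labels)) stop("labels must contain both classes")
  pr_curve(decision_values, labels)$auprc
}

#' @rdname auprc
#' @return `random_baseline()`: the positive prevalence n+/(n+ + n-).
#' @export
random_baseline <- function(labels) {
  labels <- as.logical(labels)
  if (!any(labels) || all(labels)) stop("labels must contain both classes")
  mean(labels)
}

#' Precision-recall curve from decision values
#' @inheritParams auprc
#' @return list with `curve` (data.frame `threshold`, `recall`,
#'   `precision`, recall non-decreasing) and `auprc`.
#' @export
pr_curve <- function(decision_values, labels) {
  labels <- as.logical(labels)
  o <- order(decision_values, decreasing = TRUE)
  s <- decision_values[o]; l <- labels[o]
  # group ties: cumulative counts at the last element of each tie block
  last <- cumsum(rle(s)$lengths)
  tp <- cumsum(l)[last]
  fp <- cumsum(!l)[last]
  npos <- sum(l)
  recall <- tp / npos
  precision <- tp / (tp + fp)
  ap <- sum(diff(c(0, recall)) * precision)
  list(curve = data.frame(threshold = s[last], recall = recall,
                          precision = precision),
       auprc = ap)
}

#' Stratified k-fold cross-validation of the spectrum SVM
#'
#' Assigns each class to `folds` stratified folds (reproducibly from
#' `seed`), trains on nine-tenths, scores the held-out tenth, and reports
#' one precision-recall curve per fold plus a pooled curve over all
#' held-out decision values.
#'
#' @inheritParams train_spectrum_svm
#' @param folds number of folds (default 10); each class must have at
#'   least this many members.
#' @param seed fold-assignment (and optimizer) seed.
#' @return a `cv_result` with `fold_curves`, `fold_auprc`, `auprc_min`,
#'   `auprc_max`, `pooled` (curve + auprc), `prevalence`, `seed`.
#' @export
cross_validate <- function(positives, negatives, folds = 10L,
                           config = featurizer_config(), class_weight = "auto",
                           C = 1, seed = 1L) {
  np <- length(positives); nn <- length(negatives)
  if (np < folds || nn < folds)
    stop("each class needs at least `folds` members")
  fp <- withr::with_seed(seed, sample(rep_len(seq_len(folds), np)))
  fn <- withr::with_seed(seed + 1L, sample(rep_len(seq_len(folds), nn)))
  scores <- numeric(np + nn)
  labs <- c(rep(TRUE, np), rep(FALSE, nn))
  fold_of <- c(fp, fn)
  curves <- vector("list", folds)
  for (f in seq_len(folds)) {
    model <- train_spectrum_svm(positives[fp != f], negatives[fn != f],
                                config = config, class_weight = class_weight,
                                C = C, seed = seed + f)
    held_p <- which(fp == f); held_n <- which(fn == f)
    sv <- decision_values(model, c(positives[held_p], negatives[held_n]))
    scores[c(held_p, np + held_n)] <- sv
    curves[[f]] <- pr_curve(sv, c(rep(TRUE, length(held_p)), rep(FALSE, length(held_n))))
  }
  fold_auprc <- vapply(curves, `[[`, numeric(1), "auprc")
  structure(list(fold_curves = curves, fold_auprc = fold_auprc,
                 auprc_min = min(fold_auprc), auprc_max = max(fold_auprc),
                 pooled = pr_curve(scores, labs),
                 prevalence = np / (np + nn),
                 fold_assignment = fold_of, seed = seed),
            class = "cv_result")
}

#' Rank k-mers by model weight
#'
#' Orders features by decreasing absolute weight (ties lexicographic); the
#' sign says which class a k-mer is enriched in (positive = positive class).
#'
#' @param model a `spectrum_model`.
#' @param n number of k-mers to return (default all).
#' @return data.frame `kmer`, `weight`, `sign`.
#' @export
top_kmers <- function(model, n = length(model$weights)) {
  w <- model$weights
  o <- order(-abs(w), names(w))
  o <- utils::head(o, n)
  data.frame(kmer = names(w)[o], weight = unname(w[o]),
             sign = ifelse(w[o] >= 0, "+", "-"))
}

#' Labeled CpG-context sequences from matched CpGs
#'
#' Builds the demethylated-vs-maintained classification dataset: for each
#' matched CpG (typically from the pre-methylated library) the window
#' `[pos - flank, pos + 2 + flank)` is extracted (22 bp at the default
#' flank of 10). CpGs whose ectopic rate fell below `demeth_threshold` are
#' labeled demethylated (positive); above `maint_threshold`, maintained
#' (negative); intermediate rates are excluded. Windows extending past the
#' chromosome ends are dropped and counted.
#'
#' @param matched a MatchedCpG table (see [match_cpgs()]), needing columns
#'   `chrom`, `pos`, `ectopic_rate`.
#' @param genome a [Biostrings::DNAStringSet].
#' @param flank bases on each side of the CG (default 10).
#' @param demeth_threshold,maint_threshold rate cutoffs (defaults 40/60,
#'   reusing the domain thresholds).
#' @return list with `positives`, `negatives` ([Biostrings::DNAStringSet]),
#'   `n_dropped_bounds`, `n_excluded_middle`.
#' @export
cpg_context_dataset <- function(matched, genome, flank = 10L,
                                demeth_threshold = 40, maint_threshold = 60) {
  lab <- ifelse(matched$ectopic_rate < demeth_threshold, "pos",
                ifelse(matched$ectopic_rate > maint_threshold, "neg", "mid"))
  n_mid <- sum(lab == "mid")
  keep <- lab != "mid"
  m <- matched[keep, , drop = FALSE]; lab <- lab[keep]
  chrlen <- stats::setNames(Biostrings::width(genome), names(genome))
  start <- m$pos - flank
  end <- m$pos + 2L + flank
  inb <- start >= 0L & end <= chrlen[m$chrom]
  n_oob <- sum(!inb)
  m <- m[inb, , drop = FALSE]; lab <- lab[inb]
  start <- start[inb]; end <- end[inb]
  grab <- function(sel) {
    if (!any(sel)) return(Biostrings::DNAStringSet())
    Biostrings::DNAStringSet(vapply(which(sel), function(i) {
      as.character(Biostrings::subseq(genome[[m$chrom[i]]], start[i] + 1L, end[i]))
    }, character(1)))
  }
  list(positives = grab(lab == "pos"), negatives = grab(lab == "neg"),
       n_dropped_bounds = n_oob, n_excluded_middle = n_mid)
}

#' Save / load a spectrum model as TSV
#' @param model a `spectrum_model`.
#' @param path TSV path (`kmer`, `weight`; bias and metadata in `#` header).
#' @export
write_spectrum_model <- function(model, path) {
  hdr <- sprintf("# bias=%.10g class_weight=%.10g C=%.10g k=%d mask_cpg=%s",
                 model$bias, model$class_weight, model$C, model$config$k,
                 model$config$mask_cpg)
  writeLines(c(hdr, paste(names(model$weights),
                          formatC(model$weights, format = "g", digits = 12),
                          sep = "\t")), path)
  invisible(path)
}
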