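# Brute-force reference for the domain caller: enumerate every feasible
# interval (starts and ends on a qualifying dyad, interior interleaved
# count <= maxi, qualifying count >= minq), then repeatedly emit the
# leftmost-start / longest-end interval lying strictly after the previous
# one. Independent of the caller's scan.
domain_oracle <- function(cls, minq = 10L, maxi = 4L) {
  q <- cls == "qualifying"
  qi <- which(q)
  if (!length(qi)) return(NULL)
  cumnq <- cumsum(!q)
  cumq <- cumsum(q)
  feas <- NULL
  for (i in qi) {
    j <- qi[qi >= i]
    interleaved <- cumnq[j] - cumnq[i]
    nq <- cumq[j] - cumq[i] + 1L
    ok <- interleaved <= maxi & nq >= minq
    if (any(ok))
      feas <- rbind(feas, cbind(i, j[ok], nq[ok], interleaved[ok]))
  }
  if (is.null(feas)) return(NULL)
  out <- NULL
  last_end <- 0L
  repeat {
    cand <- feas[feas[, 1] > last_end, , drop = FALSE]
    if (!nrow(cand)) break
    cand <- cand[cand[, 1] == min(cand[, 1]), , drop = FALSE]
    pick <- cand[which.max(cand[, 2]), ]
    out <- rbind(out, pick)
    last_end <- pick[2]
  }
  colnames(out) <- c("i", "j", "n_qualifying", "n_interleaved")
  out
}

# random classified track on one chromosome; rates consistent with classes
random_classified <- function(n, p = c(0.6, 0.2, 0.2)) {
  cls <- sample(c("qualifying", "nonqualifying", "undetermined"), n, TRUE, p)
  pos <- sort(sample.int(6L * n, n)) * 2L
  rate <- ifelse(cls == "qualifying", runif(n, 0, 39.9),
                 ifelse(cls == "nonqualifying", runif(n, 40, 100), NA))
  data.frame(chrom = "chr1", pos = pos, rate = rate,
             class = factor(cls, levels = c("qualifying", "nonqualifying",
                                            "undetermined")))
}

expect_matches_oracle <- function(classified, params = caller_params()) {
  got <- call_domains(classified, "hypo", params)
  exp <- domain_oracle(as.character(classified$class),
                       params$min_qualifying, params$max_interleaved)
  if (is.null(exp)) {
    expect_equal(nrow(got), 0L)
  } else {
    expect_equal(nrow(got), nrow(exp))
    expect_equal(got$start, classified$pos[exp[, "i"]])
    expect_equal(got$end, classified$pos[exp[, "j"]] + 2L)
    expect_equal(got$n_qualifying, unname(exp[, "n_qualifying"]))
    expect_equal(got$n_interleaved, unname(exp[, "n_interleaved"]))
  }
  invisible(got)
}
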