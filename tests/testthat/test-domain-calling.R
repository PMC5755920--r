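make_sites <- function(n) list(chr1 = as.integer(seq(0L, by = 2L, length.out = n)))

test_that("dyad classification applies strict thresholds and marks undetermined", {
  sites <- make_sites(5)
  tr <- methylation_track("chr1", sites$chr1[1:4],
                          c(399L, 400L, 600L, 601L), c(601L, 600L, 400L, 399L))
  # rates 39.9, 40.0, 60.0, 60.1; fifth dyad has no call
  hypo <- classify_dyads(tr, sites, "hypo")
  expect_equal(as.character(hypo$class),
               c("qualifying", "nonqualifying", "nonqualifying",
                 "nonqualifying", "undetermined"))
  hyper <- classify_dyads(tr, sites, "hyper")
  expect_equal(as.character(hyper$class),
               c("nonqualifying", "nonqualifying", "nonqualifying",
                 "qualifying", "undetermined"))

  bad <- methylation_track("chr1", 999L, 1L, 9L)
  expect_error(classify_dyads(bad, sites, "hypo"), "absent")
})

test_that("stretch definition: counts, budget and minimum size", {
  params <- caller_params()
  mk <- function(codes) {
    cls <- c(Q = "qualifying", N = "nonqualifying", U = "undetermined")[codes]
    n <- length(cls)
    data.frame(chrom = "chr1", pos = seq(0L, by = 2L, length.out = n),
               rate = ifelse(cls == "qualifying", 10,
                             ifelse(cls == "nonqualifying", 80, NA)),
               class = factor(cls, levels = c("qualifying", "nonqualifying",
                                              "undetermined")))
  }
  # ten consecutive qualifying dyads -> one domain
  d <- call_domains(mk(rep("Q", 10)), "hypo", params)
  expect_equal(nrow(d), 1L)
  expect_equal(d$n_qualifying, 10L)
  expect_equal(d$n_interleaved, 0L)
  expect_equal(d$start, 0L)
  expect_equal(d$end, 18L + 2L)
  # nine are not enough
  expect_equal(nrow(call_domains(mk(rep("Q", 9)), "hypo", params)), 0L)
  # five interleaved split two stretches; four do not
  d2 <- call_domains(mk(c(rep("Q", 12), rep("N", 5), rep("Q", 12))), "hypo", params)
  expect_equal(nrow(d2), 2L)
  expect_equal(d2$n_qualifying, c(12L, 12L))
  d3 <- call_domains(mk(c(rep("Q", 6), rep("N", 2), rep("Q", 6))), "hypo", params)
  expect_equal(nrow(d3), 1L)
  expect_equal(d3$n_qualifying, 12L)
  expect_equal(d3$n_interleaved, 2L)
  # undetermined dyads spend the same budget
  d4 <- call_domains(mk(c(rep("Q", 6), rep("U", 5), rep("Q", 6))), "hypo", params)
  expect_equal(nrow(d4), 0L)
})

test_that("hypo and hyper are called independently over the same dyads", {
  n <- 15L
  g <- Biostrings::DNAStringSet(c(chr1 = paste(rep("CGT", n), collapse = "")))
  pos <- seq(0L, by = 3L, length.out = n)
  all0 <- methylation_track("chr1", pos, rep(0L, n), rep(10L, n))
  res <- call_all(all0, g)
  expect_equal(nrow(res$hypo), 1L)
  expect_equal(res$hypo$n_qualifying, n)
  expect_equal(nrow(res$hyper), 0L)

  all100 <- methylation_track("chr1", pos, rep(10L, n), rep(0L, n))
  res <- call_all(all100, g)
  expect_equal(nrow(res$hyper), 1L)
  expect_equal(nrow(res$hypo), 0L)

  alt <- methylation_track("chr1", pos, as.integer(10 * (seq_len(n) %% 2)),
                           as.integer(10 * (1 - seq_len(n) %% 2)))
  res <- call_all(alt, g)
  expect_equal(nrow(res$hypo), 0L)
  expect_equal(nrow(res$hyper), 0L)
})

test_that("greedy caller equals the brute-force oracle on random tracks", {
  set.seed(101)
  for (rep in 1:200) {
    cl <- random_classified(sample(20:200, 1))
    expect_matches_oracle(cl)
  }
})

test_that("emitted domains are non-extendable, disjoint and well separated", {
  params <- caller_params()
  set.seed(202)
  for (rep in 1:200) {
    cl <- random_classified(sample(30:200, 1))
    d <- call_domains(cl, "hypo", params)
    if (!nrow(d)) next
    idx_s <- match(d$start, cl$pos)
    idx_e <- match(d$end - 2L, cl$pos)
    # first and last dyads are qualifying
    expect_true(all(cl$class[idx_s] == "qualifying"))
    expect_true(all(cl$class[idx_e] == "qualifying"))
    # budget respected
    expect_true(all(d$n_interleaved <= params$max_interleaved))
    expect_true(all(d$n_qualifying >= params$min_qualifying))
    # one-dyad extension impossible: the dyad just left of a start is
    # never a free qualifying dyad (it is absent or non-qualifying or the
    # previous domain's last dyad), and a qualifying dyad just right of an
    # end can only occur if the budget was already spent beyond the limit
    for (k in seq_len(nrow(d))) {
      l <- idx_s[k] - 1L
      if (l >= 1 && cl$class[l] == "qualifying")
        expect_true(k > 1 && cl$pos[l] == d$end[k - 1] - 2L)
      r <- idx_e[k] + 1L
      if (r <= nrow(cl) && cl$class[r] == "qualifying")
        fail("domain extendable by an adjacent qualifying dyad")
    }
    # disjoint and ordered
    if (nrow(d) > 1) expect_true(all(d$start[-1] > d$end[-nrow(d)]))
  }
})

test_that("relaxing the interleave budget enlarges the feasible-interval set", {
  # feasibility is monotone in the budget (each emitted segment still obeys
  # the caller's left-to-right tie-break, so *realized* coverage can dip
  # when a longer first domain strands a short tail -- see below)
  set.seed(303)
  for (rep in 1:30) {
    cl <- random_classified(sample(50:150, 1))
    n_feas <- vapply(c(2L, 4L, 6L), function(mi) {
      o <- domain_oracle(as.character(cl$class), maxi = mi)
      if (is.null(o)) 0L else nrow(o)
    }, integer(1))
    d <- lapply(c(2L, 4L, 6L), function(mi)
      call_domains(cl, "hypo", caller_params(max_interleaved = mi)))
    # every domain called under a smaller budget is feasible under a larger
    for (k in 1:2) {
      if (!nrow(d[[k]])) next
      for (i in seq_len(nrow(d[[k]])))
        expect_lte(d[[k]]$n_interleaved[i], c(4L, 6L)[k])
    }
  }

  # documented left-to-right behavior: a larger budget can merge across a
  # gap and strand a tail shorter than the minimum, lowering coverage
  codes <- c(rep("Q", 10), rep("N", 5), rep("Q", 6),
             rep(c("N", "Q"), 4))
  cls <- c(Q = "qualifying", N = "nonqualifying")[codes]
  cl <- data.frame(chrom = "chr1",
                   pos = seq(0L, by = 2L, length.out = length(cls)),
                   rate = ifelse(cls == "qualifying", 10, 80),
                   class = factor(cls, levels = c("qualifying",
                                                  "nonqualifying",
                                                  "undetermined")))
  d4 <- call_domains(cl, "hypo", caller_params(max_interleaved = 4L))
  d5 <- call_domains(cl, "hypo", caller_params(max_interleaved = 5L))
  expect_equal(sum(d4$n_qualifying), 20L)
  expect_equal(sum(d5$n_qualifying), 16L)
})

test_that("domain summaries report length, GC and CpG density", {
  g <- Biostrings::DNAStringSet(c(chr1 = paste(rep("CG", 500), collapse = "")))
  doms <- data.frame(chrom = "chr1", start = 0L, end = 1000L, kind = "hypo",
                     n_qualifying = 10L, n_interleaved = 0L, mean_rate = 0)
  tr <- methylation_track("chr1", c(0L, 2L), c(0L, 0L), c(10L, 10L))
  s <- domain_summaries(doms, tr, g)
  expect_equal(s$length, 1000L)
  expect_equal(s$gc, 1.0)
  expect_equal(s$cpg_density, 500)
  expect_equal(s$mean_rate, 0)
  empty <- domain_summaries(doms[0, ], tr, g)
  expect_equal(nrow(empty), 0L)
})
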