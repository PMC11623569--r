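test_that("isolate caller applies the printed thresholds verbatim", {
  # all filters pass: depth 100/50 >= 20, del 10 >= 5, 10% >= 5%, 0% < 1%
  pair <- mk_site_pair(100L, 10L, 50L, 0L)
  calls <- call_sites_isolate(pair$treated, pair$untreated)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$strand, "+")
  expect_equal(calls$psi_proportion, 0.10)

  # untreated 2% violates the strict < 1% rule
  pair <- mk_site_pair(100L, 10L, 50L, 1L)
  expect_equal(nrow(call_sites_isolate(pair$treated, pair$untreated)), 0L)

  # untreated fraction exactly 1% is excluded (strict inequality)
  pair <- mk_site_pair(100L, 10L, 100L, 1L)
  expect_equal(nrow(call_sites_isolate(pair$treated, pair$untreated)), 0L)

  # treated deletion count below 5 is excluded even at high fraction
  pair <- mk_site_pair(40L, 4L, 40L, 0L)
  expect_equal(nrow(call_sites_isolate(pair$treated, pair$untreated)), 0L)

  # depth below 20 in either sample is excluded
  pair <- mk_site_pair(100L, 10L, 19L, 0L)
  expect_equal(nrow(call_sites_isolate(pair$treated, pair$untreated)), 0L)
})

test_that("only uridine positions are candidates, with strand from the base", {
  # genomic A = U on the minus strand; genomic C/G are never candidates
  for (b in c("A", "C", "G")) {
    pair <- mk_site_pair(100L, 10L, 50L, 0L, base = b)
    calls <- call_sites_isolate(pair$treated, pair$untreated)
    if (b == "A") {
      expect_equal(calls$strand, "-")
    } else {
      expect_equal(nrow(calls), 0L)
    }
  }
})

test_that("a position absent from the untreated table fails depth, not errors", {
  treated <- pileup_table("chr1", c(100L, 200L), "T", c(100L, 100L),
                          c(10L, 10L), "trt")
  untreated <- pileup_table("chr1", 100L, "T", 100L, 0L, "untx")
  calls <- call_sites_isolate(treated, untreated)
  expect_equal(calls$pos, 100L)
})

test_that("one-sided Fisher p matches hand-derived and degenerate tables", {
  # [[2,0],[0,2]]: P(X >= 2), X ~ Hypergeom(N=4, K=2, n=2) = 1/6
  expect_equal(fisher_exact_one_sided(2, 0, 0, 2), 1 / 6, tolerance = 1e-12)
  # no deletions anywhere: enrichment impossible
  expect_equal(fisher_exact_one_sided(0, 10, 0, 10), 1)
  # symmetric table: no enrichment, p well above 0.5
  expect_gt(fisher_exact_one_sided(5, 5, 5, 5), 0.5)
  # agrees with stats::fisher.test one-sided on a non-trivial table
  ft <- fisher.test(matrix(c(10, 90, 2, 98), 2, byrow = TRUE),
                    alternative = "greater")
  expect_equal(fisher_exact_one_sided(10, 90, 2, 98), ft$p.value,
               tolerance = 1e-12)
})

test_that("microbiome caller combines fold, count and Fisher filters", {
  th <- call_thresholds("microbiome")
  # fold 5 >= 2 and p < 0.01: called, proportion is the delta fraction
  pair <- mk_site_pair(100L, 20L, 100L, 2L)
  calls <- call_sites_microbiome(pair$treated, pair$untreated, th)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$psi_proportion, 0.18)
  expect_equal(calls$p_value, fisher_exact_one_sided(20, 80, 2, 98))
  expect_lt(calls$p_value, 0.01)

  # decision follows the computed p: fold passes but p >= 0.01 -> not called
  pair <- mk_site_pair(100L, 10L, 100L, 2L)
  p <- fisher_exact_one_sided(10, 90, 2, 98)
  calls <- call_sites_microbiome(pair$treated, pair$untreated, th)
  expect_equal(nrow(calls), as.integer(p < 0.01))

  # fold below 2 -> not called
  pair <- mk_site_pair(100L, 10L, 100L, 6L)
  expect_equal(nrow(call_sites_microbiome(pair$treated, pair$untreated, th)),
               0L)
  # deletion count below 5 -> not called
  pair <- mk_site_pair(100L, 4L, 100L, 0L)
  expect_equal(nrow(call_sites_microbiome(pair$treated, pair$untreated, th)),
               0L)
  # untreated fraction exactly 0 passes the fold filter by convention
  pair <- mk_site_pair(100L, 20L, 100L, 0L)
  expect_equal(nrow(call_sites_microbiome(pair$treated, pair$untreated, th)),
               1L)
})

test_that("high-confidence aggregation counts distinct treated samples", {
  pair1 <- mk_site_pair(100L, 10L)
  pair2 <- mk_site_pair(80L, 12L)
  c1 <- call_sites_isolate(pair1$treated, pair1$untreated)
  c2 <- call_sites_isolate(pair2$treated, pair2$untreated)
  # replicate support from a biological replicate or another condition
  hc <- aggregate_high_confidence(list(rep1_37C = c1, rep1_amp = c2), 2L)
  expect_equal(nrow(hc), 1L)
  expect_equal(hc$n_supporting, 2L)
  expect_true(hc$high_confidence)
  expect_equal(hc$supporting_samples, "rep1_37C,rep1_amp")
  expect_equal(hc$treated_frac, mean(c(0.10, 0.15)))

  # a site seen in one sample only is excluded at the default of 2
  hc1 <- aggregate_high_confidence(list(rep1 = c1), 2L)
  expect_equal(nrow(hc1), 0L)
})

test_that("aggregation output is a subset and min_samples = 1 the union", {
  set.seed(5)
  pairs <- lapply(1:3, function(i) mk_random_pair(40L, seed = i))
  calls <- lapply(pairs, function(p) {
    call_sites_isolate(p$treated, p$untreated,
                       call_thresholds("isolate", min_treated_fraction = 0.02,
                                       min_del_count = 2))
  })
  names(calls) <- paste0("s", 1:3)
  union_keys <- unique(unlist(lapply(calls, function(cc) {
    paste(cc$ref, cc$pos, cc$strand)
  })))
  for (k in 1:3) {
    hc <- aggregate_high_confidence(calls, k)
    expect_true(all(paste(hc$ref, hc$pos, hc$strand) %in% union_keys))
  }
  hc1 <- aggregate_high_confidence(calls, 1L)
  expect_setequal(paste(hc1$ref, hc1$pos, hc1$strand), union_keys)
})

test_that("homopolymer runs are flagged and left-aligned", {
  ref <- c(chr1 = "GACTTTGAGCTAGAAGC")  # TTT run at 4-6, lone T at 12
  calls <- data.frame(ref = "chr1", pos = c(5L, 12L, 15L),
                      strand = c("+", "+", "-"),
                      stringsAsFactors = FALSE)
  out <- flag_homopolymer_ambiguity(calls, ref, reposition = TRUE)
  expect_equal(out$homopolymer, c(TRUE, FALSE, TRUE))
  expect_equal(out$pos[1], 4L)   # leftmost U of the TTT run
  expect_equal(out$pos[2], 12L)  # isolated U untouched
  expect_equal(out$pos[3], 14L)  # AA run on minus strand, leftmost A
  # a run of exactly two is already ambiguous
  ref2 <- c(chr1 = "GATTGAG")
  out2 <- flag_homopolymer_ambiguity(
    data.frame(ref = "chr1", pos = 4L, strand = "+"), ref2)
  expect_true(out2$homopolymer)
})

test_that("tightening any single threshold never increases call count", {
  for (seed in 1:25) {
    pair <- mk_random_pair(40L, seed = seed)
    for (mode in c("isolate", "microbiome")) {
      base_th <- call_thresholds(mode)
      baseline <- nrow(call_sites_engine_for_test(pair, base_th))
      tighter <- list(
        call_thresholds(mode, min_depth = 40L),
        call_thresholds(mode, min_del_count = 8L),
        call_thresholds(mode, min_treated_fraction =
                          base_th$min_treated_fraction + 0.03))
      if (mode == "isolate") {
        tighter <- c(tighter, list(
          call_thresholds(mode, max_untreated_fraction = 0.005)))
      } else {
        tighter <- c(tighter, list(
          call_thresholds(mode, min_fold = 4),
          call_thresholds(mode, max_p = 0.001)))
      }
      for (th in tighter) {
        expect_lte(nrow(call_sites_engine_for_test(pair, th)), baseline)
      }
    }
  }
})
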