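test_that("psi strength is the sum of site fractions", {
  expect_equal(psi_strength(c(0.10, 0.25)), 0.35)
  expect_equal(psi_strength(numeric()), 0)
  expect_equal(psi_strength(0.07), 0.07)
  expect_error(psi_strength(c(0.1, 1.2)), "\\[0,1\\]")
  # permutation invariance and additivity under concatenation
  set.seed(3)
  x <- runif(10); y <- runif(5)
  expect_equal(psi_strength(sample(x)), psi_strength(x))
  expect_equal(psi_strength(c(x, y)), psi_strength(x) + psi_strength(y))
})

test_that("TPM matches the hand-derived two-gene example and sums to 1e6", {
  counts <- c(g1 = 10, g2 = 20)
  lengths <- c(g1 = 1000, g2 = 2000)
  # rates 11/1000 and 21/2000 -> 511627.9 / 488372.1
  out <- tpm(counts, lengths, pseudocount = 1)
  expect_equal(unname(out["g1"]), 0.011 / 0.0215 * 1e6, tolerance = 1e-10)
  expect_equal(unname(out["g2"]), 0.0105 / 0.0215 * 1e6, tolerance = 1e-10)
  expect_equal(sum(out), 1e6)

  # symmetry: zero counts at equal lengths
  out0 <- tpm(c(a = 0, b = 0, c = 0), c(a = 500, b = 500, c = 500))
  expect_equal(unname(out0), rep(1e6 / 3, 3))

  set.seed(9)
  m <- matrix(rpois(300, 50), 100, 3,
              dimnames = list(sprintf("g%03d", 1:100), NULL))
  lens <- setNames(sample(200:3000, 100), rownames(m))
  tm <- tpm(m, lens)
  expect_equal(unname(colSums(tm)), rep(1e6, 3), tolerance = 1e-6)
})

test_that("the microbiome prefilter drops genes under 5 reads in all samples", {
  m <- matrix(c(3, 4,    # below 5 everywhere -> removed
                3, 7,    # reaches 5 in one sample -> kept
                50, 60), 3, 2, byrow = TRUE,
              dimnames = list(c("low", "mid", "high"), NULL))
  lens <- c(low = 1000, mid = 1000, high = 1000)
  out <- tpm(m, lens, min_reads_prefilter = 5)
  expect_setequal(rownames(out), c("mid", "high"))
  expect_equal(unname(colSums(out)), rep(1e6, 2), tolerance = 1e-6)
  expect_error(tpm(c(g = 1), c(x = 100)), "no length.*g")
})

test_that("per-gene profiles assign same-strand sites and compute density", {
  ann <- annotation_set(c("gA", "gB"), "chr1", c(1L, 2001L), c(1000L, 2500L),
                        c("+", "-"))
  calls <- data.frame(ref = "chr1", pos = c(100L, 300L, 2100L, 500L),
                      strand = c("+", "+", "-", "-"),
                      psi_proportion = c(0.1, 0.2, 0.3, 0.4),
                      stringsAsFactors = FALSE)
  prof <- transcript_psi_profiles(calls, ann, c(gA = 50, gB = 20))
  gA <- prof[prof$gene_id == "gA", ]
  gB <- prof[prof$gene_id == "gB", ]
  # the minus-strand call at 500 is antisense to gA and must not count
  expect_equal(gA$n_sites, 2L)
  expect_equal(gA$psi_strength, 0.3)
  expect_equal(gA$sites_per_kb, 2 * 1000 / 1000)
  expect_equal(gB$n_sites, 1L)
  expect_equal(gB$tpm, 20)
  # psi_strength >= max site fraction by construction
  expect_gte(gA$psi_strength, 0.2)
})

test_that("PUS assignment needs the delta in every replicate", {
  prof <- function(s) data.frame(gene_id = "g1", psi_strength = s)
  res <- assign_pus(list(prof(0.20), prof(0.22)),
                    list(prof(0.05), prof(0.08)), pus_name = "truB")
  expect_true(res$assigned)
  expect_equal(c(res$delta_rep1, res$delta_rep2), c(0.15, 0.14))

  # one replicate below 0.05 -> not assigned
  res2 <- assign_pus(list(prof(0.20), prof(0.22)),
                     list(prof(0.17), prof(0.10)))
  expect_false(res2$assigned)
  # identical profiles -> zero delta -> not assigned
  expect_false(assign_pus(list(prof(0.2)), list(prof(0.2)))$assigned)
  # replicate structure must match
  expect_error(assign_pus(list(prof(0.2)), list(prof(0.2), prof(0.2))),
               "replicate mismatch")
  # a gene absent from the mutant contributes strength 0 (union of sites)
  res3 <- assign_pus(list(prof(0.2)),
                     list(data.frame(gene_id = "other", psi_strength = 1)))
  expect_true(res3$assigned[res3$gene_id == "g1"])
})

test_that("stress differential mirrors the rule and flags near-miss controls", {
  prof <- function(s) data.frame(gene_id = "g1", psi_strength = s)
  res <- differential_stress(list(prof(0.12), prof(0.09)),
                             list(prof(0), prof(0)))
  expect_true(res$increased)
  expect_false(res$review_flag)

  res2 <- differential_stress(list(prof(0.12), prof(0.03)),
                              list(prof(0), prof(0)))
  expect_false(res2$increased)

  expect_false(differential_stress(list(prof(0.1)), list(prof(0.1)))$increased)

  # control signal close to the cutoff is reported but flagged for review
  res3 <- differential_stress(list(prof(0.10), prof(0.10)),
                              list(prof(0.03), prof(0.0)))
  expect_true(res3$increased)
  expect_true(res3$review_flag)
})

test_that("contrast thresholds are monotone: raising min_delta never adds", {
  set.seed(21)
  mk <- function() {
    data.frame(gene_id = sprintf("g%02d", 1:20),
               psi_strength = runif(20, 0, 0.4))
  }
  wt <- list(mk(), mk()); mu <- list(mk(), mk())
  deltas <- seq(0.01, 0.2, by = 0.01)
  n_assigned <- vapply(deltas, function(d) {
    sum(assign_pus(wt, mu, min_delta = d)$assigned)
  }, numeric(1))
  expect_true(all(diff(n_assigned) <= 0))
})

test_that("dot-bracket pairing classification and bounds", {
  expect_equal(pairing_class("((...))", 3), "unpaired")
  expect_equal(pairing_class("((...))", 1), "paired")
  expect_equal(pairing_class("((...))", 7), "paired")
  expect_error(pairing_class("((...))", 8), "outside")
  expect_warning(pairing_class("((...", 2), "unbalanced")
  expect_error(pairing_class("((x..))", 1), "dot-bracket")
})

test_that("spearman correlations match the rank formula and handle ties", {
  prof <- data.frame(gene_id = letters[1:5],
                     sites_per_kb = c(1, 2, 3, 4, 5),
                     mean_site_proportion = c(0.5, 0.4, 0.3, 0.2, 0.1),
                     tpm = c(10, 20, 30, 40, 50))
  res <- sites_vs_abundance(prof)
  expect_equal(res$rho[res$metric == "sites_per_kb"], 1)
  expect_equal(res$rho[res$metric == "psi_level"], -1)

  # 5 hand-ranked tie-free pairs against the textbook formula
  set.seed(31)
  x <- sample(1:50, 5); y <- sample(1:50, 5)
  prof2 <- data.frame(gene_id = letters[1:5], sites_per_kb = x,
                      mean_site_proportion = runif(5), tpm = y)
  res2 <- sites_vs_abundance(prof2)
  expect_equal(res2$rho[res2$metric == "sites_per_kb"],
               oracle_spearman(x, y), tolerance = 1e-12)

  # constant vector -> correlation undefined, reported as missing
  prof3 <- prof
  prof3$sites_per_kb <- 2
  res3 <- sites_vs_abundance(prof3)
  expect_true(is.na(res3$rho[res3$metric == "sites_per_kb"]))
  expect_error(sites_vs_abundance(prof[1:2, ]), ">= 3")
})
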