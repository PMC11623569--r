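## tiny in-code fixtures and independent oracles shared across test files

## one-row pileup pair around a single uridine site
mk_site_pair <- function(depth_t = 100L, del_t = 10L, depth_u = 100L,
                         del_u = 0L, base = "T", pos = 100L) {
  list(
    treated = pileup_table("chr1", pos, base, depth_t, del_t, "trt"),
    untreated = pileup_table("chr1", pos, base, depth_u, del_u, "untx"))
}

## random small pileup pair over a fixed base layout (for property tests)
mk_random_pair <- function(n = 30L, seed = 1L) {
  set.seed(seed)
  base <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  depth_t <- sample(5:200, n, replace = TRUE)
  depth_u <- sample(5:200, n, replace = TRUE)
  del_t <- rbinom(n, depth_t, runif(n, 0, 0.15))
  del_u <- rbinom(n, depth_u, runif(n, 0, 0.03))
  list(
    treated = pileup_table("c", seq_len(n), base, depth_t, del_t, "trt"),
    untreated = pileup_table("c", seq_len(n), base, depth_u, del_u, "untx"))
}

## brute-force one-sided Fisher p: explicit sum of hypergeometric terms over
## all tables at least as extreme as observed (deletion enrichment in treated)
oracle_fisher <- function(a, b, c_, d) {
  N <- a + b + c_ + d; K <- a + c_; n <- a + b
  j <- a:min(K, n)
  sum(exp(lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n)))
}

## exact two-sided rank-sum p by enumeration of all C(n1+n2, n1) group
## assignments of the pooled observations (tie-free inputs)
oracle_wilcox <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  splits <- utils::combn(n1 + n2, n1)
  w_null <- apply(splits, 2L, function(i) sum(r[i])) - n1 * (n1 + 1) / 2
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  lo <- mean(w_null <= w_obs); hi <- mean(w_null >= w_obs)
  min(1, 2 * min(lo, hi))
}

## textbook Spearman rho without ties: 1 - 6*sum(d^2)/(n(n^2-1))
oracle_spearman <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

## run the caller matching a thresholds object's mode
call_sites_engine_for_test <- function(pair, th) {
  if (th$mode == "isolate") {
    call_sites_isolate(pair$treated, pair$untreated, th)
  } else {
    call_sites_microbiome(pair$treated, pair$untreated, th)
  }
}

## small deterministic reference for motif/homopolymer tests
mk_reference <- function(seqs = c(chr1 = "AAGGTATCCTTTGACGTACGT")) seqs
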