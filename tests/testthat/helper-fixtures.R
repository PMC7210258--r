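# Shared fixtures and independent oracles. Oracles are deliberately written
# as brute-force enumeration/lattice search, independent of the package's
# closed forms.

# lattice maximization of the joint binomial log-likelihood over (m, h),
# coarse-to-fine down to a 1e-4 grid (the likelihood is log-concave, so
# local refinement around the coarse optimum is safe)
grid_mle_oracle <- function(beta_bs, n_bs, beta_ox, n_ox) {
  x_bs <- round(beta_bs * n_bs); x_ox <- round(beta_ox * n_ox)
  ll <- function(m, h) {
    dbinom(x_bs, n_bs, pmin(pmax(m + h, 0), 1), log = TRUE) +
      dbinom(x_ox, n_ox, pmin(pmax(m, 0), 1), log = TRUE)
  }
  refine <- function(mlo, mhi, hlo, hhi, step) {
    snap <- function(v) round(v / step) * step
    g <- expand.grid(m = seq(snap(max(0, mlo)), snap(min(1, mhi)), by = step),
                     h = seq(snap(max(0, hlo)), snap(min(1, hhi)), by = step))
    g <- g[g$m + g$h <= 1 + 1e-12 & g$m >= 0 & g$h >= 0, ]
    g[which.max(ll(g$m, g$h)), ]
  }
  b <- refine(0, 1, 0, 1, 0.01)
  b <- refine(b$m - 0.02, b$m + 0.02, b$h - 0.02, b$h + 0.02, 1e-3)
  b <- refine(b$m - 2e-3, b$m + 2e-3, b$h - 2e-3, b$h + 2e-3, 1e-4)
  list(m = b$m, h = b$h)
}

# exact two-sided Mann-Whitney p by full enumeration of group labelings
wilcoxon_enum_oracle <- function(a, b) {
  pooled <- c(a, b); n1 <- length(a)
  r <- rank(pooled)
  u_of <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(length(pooled), n1)
  us <- apply(combos, 2, u_of)
  u_obs <- u_of(seq_len(n1))
  mu <- n1 * length(b) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# hand Benjamini-Hochberg: p(i)*m/i then cumulative min from the largest rank
bh_oracle <- function(p) {
  m <- length(p); o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m); out[o] <- pmin(adj, 1)
  out
}

# exact upper-tail hypergeometric by direct summation
hyper_tail_oracle <- function(k, nA, nB, nU) {
  j <- k:min(nA, nB)
  sum(choose(nA, j) * choose(nU - nA, nB - j)) / choose(nU, nB)
}

# two-sided Fisher p for a 2x2 table by enumerating all tables with the
# observed margins
fisher_enum_oracle <- function(a, b, c, d) {
  m <- a + c; n <- b + d; k <- a + b
  xs <- max(0, k - n):min(k, m)
  probs <- dhyper(xs, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# hand-built ground truth for planted-peak simulations: `h` and `m` are
# probes x 1 matrices (single condition), positions regular on one chrom
make_flat_truth <- function(h, m, spacing = 500L, condition = "cond") {
  n <- length(h)
  pos <- seq(1000L, by = spacing, length.out = n)
  probes <- data.frame(probe_id = sprintf("cg%06d", seq_len(n)),
                       chrom = "chr1", pos = pos,
                       class_label = "body", gene_id = NA_character_,
                       subunit = NA_character_, feature = "intron",
                       block_id = NA_integer_, stringsAsFactors = FALSE)
  rownames(probes) <- probes$probe_id
  structure(list(probes = probes,
                 m = matrix(m, n, 1, dimnames = list(probes$probe_id, condition)),
                 h = matrix(h, n, 1, dimnames = list(probes$probe_id, condition)),
                 conditions = condition, blocks = NULL),
            class = "truth_methylome")
}

flat_sim_config <- function(seed, coverage = 1000L, cultures = 3L,
                            condition = "cond", fail_rate = 0,
                            bad_frac = 0) {
  reps <- stats::setNames(as.integer(cultures), condition)
  sim_config(seed = seed, coverage = coverage, replicates = reps,
             h_body = stats::setNames(0.05, condition),
             m_body = stats::setNames(0.3, condition),
             detection_fail_rate = fail_rate, bad_probe_frac = bad_frac,
             n_planted_blocks = 0L)
}

# small default dataset shared by several tests (generated once per run)
default_small_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- run_pipeline(pipeline_config(seed = 1), quiet = TRUE)
    cache
  }
})
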