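# relabel a sheet so a BS matrix can stand in for both channels
transform_sheet_bs_as_ox <- function(sheet) {
  sheet$sample_id[sheet$channel == "oxBS"] <-
    sheet$sample_id[sheet$channel == "BS"]
  sheet
}

test_that("naive paired delta subtracts oxBS from BS and keeps negatives", {
  arr <- (function() {
    ann <- generate_annotation(seed = 9, n_genes = 5, chrom_length = 5e5)
    cfg <- sim_config(seed = 9)
    simulate_paired_arrays(generate_truth(ann, cfg), cfg)
  })()
  d <- naive_delta(arr$bs, arr$oxbs, arr$samples)
  pairs <- attr(d, "pairs")
  expect_equal(d[, 1],
               arr$bs$beta[, pairs$bs_sample[1]] -
                 arr$oxbs$beta[, pairs$ox_sample[1]])
  expect_true(all(d >= -1 & d <= 1))
  expect_true(any(d < 0))  # negatives retained at this stage

  same <- naive_delta(arr$bs, arr$bs, transform_sheet_bs_as_ox(arr$samples))
  expect_true(all(same == 0))
})

test_that("the binomial MLE matches its closed form, the NA rule, and a lattice oracle", {
  # interior closed form
  est <- oxbs_mle(0.5, 100, 0.3, 100)
  expect_equal(est$m_hat, 0.3)
  expect_equal(est$h_hat, 0.2)
  # simplex corner
  est2 <- oxbs_mle(1.0, 50, 0.0, 50)
  expect_equal(est2$m_hat, 0.0)
  expect_equal(est2$h_hat, 1.0)
  # boundary case: negative naive difference gives NA 5hmC and pooled 5mC
  est3 <- oxbs_mle(0.2, 100, 0.4, 300)
  expect_true(is.na(est3$h_hat))
  expect_equal(est3$m_hat, (20 + 120) / 400)
  # validation
  expect_error(oxbs_mle(0.5, 0, 0.3, 100), class = "oxbspipe_validation_error")

  # lattice-oracle agreement on random inputs, including small coverages
  set.seed(101)
  for (i in 1:200) {
    n_bs <- sample(c(10, 50, 100, 1000), 1)
    n_ox <- sample(c(10, 50, 100, 1000), 1)
    b_bs <- runif(1); b_ox <- runif(1)
    mine <- oxbs_mle(b_bs, n_bs, b_ox, n_ox)
    orc <- grid_mle_oracle(b_bs, n_bs, b_ox, n_ox)
    expect_lt(abs(mine$m_hat - orc$m), 1e-3 + 1e-9)
    if (is.na(mine$h_hat)) expect_lt(orc$h, 1e-3 + 1e-9) else
      expect_lt(abs(mine$h_hat - orc$h), 1e-3 + 1e-9)
  }
})

test_that("methylome estimation respects the simplex, the NA mask, and consistency", {
  ann <- generate_annotation(seed = 13, n_genes = 10, chrom_length = 1e6)
  cfg <- sim_config(seed = 13)
  tr <- generate_truth(ann, cfg)
  arr <- simulate_paired_arrays(tr, cfg)
  est <- suppressMessages(estimate_methylome(arr$bs, arr$oxbs, arr$samples))

  ok <- !is.na(est$h)
  expect_true(all(est$m[ok] + est$h[ok] <= 1 + 1e-12))
  expect_true(all(est$m[ok] >= 0 & est$h[ok] >= 0))

  # the NA mask is exactly the negative-difference set
  d <- naive_delta(arr$bs, arr$oxbs, arr$samples)
  expect_identical(unname(est$na_mask), unname(d < 0))
  # where defined, the 5hmC MLE is exactly the naive paired difference
  expect_equal(est$h[ok], d[ok])

  # high-coverage consistency
  cfgN <- sim_config(seed = 13, coverage = 1e7L, detection_fail_rate = 0,
                     bad_probe_frac = 0)
  trN <- generate_truth(ann, cfgN)
  arrN <- simulate_paired_arrays(trN, cfgN)
  estN <- estimate_methylome(arrN$bs, arrN$oxbs, arrN$samples, quiet = TRUE)
  for (cc in cfgN$conditions) {
    cols <- estN$pairs$pair_id[estN$pairs$condition == cc]
    hh <- estN$h[, cols]
    okN <- !is.na(hh)
    expect_lt(max(abs(hh[okN] - trN$h[, cc][row(hh)[okN]])), 0.002)
  }

  # a hydroxymethylation-free methylome leaves the sign of the difference
  # to noise: NA fraction lands near one half
  tr0 <- make_flat_truth(h = rep(0, 400), m = rep(0.4, 400))
  cfg0 <- flat_sim_config(seed = 4, cultures = 2L)
  arr0 <- simulate_paired_arrays(tr0, cfg0)
  est0 <- estimate_methylome(arr0$bs, arr0$oxbs, arr0$samples, quiet = TRUE)
  expect_gt(mean(est0$na_mask), 0.2)
  expect_lt(mean(est0$na_mask), 0.8)
})

test_that("global 5hmC signal loss matches its definition and invariances", {
  tr <- make_flat_truth(h = rep(0.05, 300), m = rep(0.45, 300))
  cfg <- flat_sim_config(seed = 21, cultures = 2L)
  arr <- simulate_paired_arrays(tr, cfg)

  # identical matrices lose nothing
  sheet0 <- arr$samples
  sheet0$sample_id[sheet0$channel == "oxBS"] <-
    sheet0$sample_id[sheet0$channel == "BS"]
  loss0 <- global_hmc_loss(arr$bs, arr$bs, sheet0)
  expect_equal(loss0$loss, 0)

  # plain arithmetic: mean BS 0.50, mean oxBS 0.45 -> loss 0.10
  probes <- arr$bs$probes
  bs_c <- beta_matrix(matrix(0.50, 300, 2,
                             dimnames = list(probes$probe_id, c("a_BS", "b_BS"))),
                      matrix(0, 300, 2), 100, probes, "BS")
  ox_c <- beta_matrix(matrix(0.45, 300, 2,
                             dimnames = list(probes$probe_id, c("a_oxBS", "b_oxBS"))),
                      matrix(0, 300, 2), 100, probes, "oxBS")
  sheet_c <- data.frame(sample_id = c("a_BS", "b_BS", "a_oxBS", "b_oxBS"),
                        culture = c("a", "b", "a", "b"), condition = "x",
                        channel = c("BS", "BS", "oxBS", "oxBS"))
  expect_equal(global_hmc_loss(bs_c, ox_c, sheet_c)$loss, 0.1)

  # tracks true h / (m + h) on the simulation
  loss <- global_hmc_loss(arr$bs, arr$oxbs, arr$samples)
  expect_lt(abs(loss$loss - 0.05 / 0.50), 0.02)

  # invariant to probe reordering and to duplicating all samples
  perm <- sample(nrow(arr$bs$beta))
  expect_equal(global_hmc_loss(arr$bs[perm], arr$oxbs[perm], arr$samples)$loss,
               loss$loss)
  dup <- function(bm, suffix) {
    b2 <- bm
    b2$beta <- cbind(bm$beta, `colnames<-`(bm$beta, paste0(colnames(bm$beta), suffix)))
    b2$detection_p <- cbind(bm$detection_p,
                            `colnames<-`(bm$detection_p,
                                         paste0(colnames(bm$detection_p), suffix)))
    b2$coverage <- cbind(bm$coverage,
                         `colnames<-`(bm$coverage,
                                      paste0(colnames(bm$coverage), suffix)))
    b2
  }
  sheet_dup <- rbind(arr$samples,
                     transform(arr$samples,
                               sample_id = paste0(sample_id, "_dup"),
                               culture = paste0(culture, "_dup")))
  expect_equal(global_hmc_loss(dup(arr$bs, "_dup"), dup(arr$oxbs, "_dup"),
                               sheet_dup)$loss, loss$loss)

  # zero BS signal is an explicit error
  bs0 <- bs_c; bs0$beta[] <- 0
  expect_error(global_hmc_loss(bs0, ox_c, sheet_c),
               class = "oxbspipe_validation_error")
})

test_that("5hmC peak calls require both significance and the minimum delta", {
  set.seed(7)
  n <- 300
  delta <- matrix(rnorm(n * 3, 0, 0.02), n, 3,
                  dimnames = list(sprintf("p%03d", 1:n), c("c1", "c2", "c3")))
  delta["p001", ] <- c(0.20, 0.21, 0.19)   # strong stable gain -> peak
  delta["p002", 1:2] <- c(0.05, 0.06)      # below min_delta -> never a peak
  calls <- call_hmc_peaks(delta, min_delta = 0.10, alpha = 0.05)
  expect_true(calls$is_peak[calls$probe_id == "p001"])
  expect_false(calls$is_peak[calls$probe_id == "p002"])

  # with thresholds fully open, every positive-mean probe is called
  open <- call_hmc_peaks(delta, min_delta = 0, alpha = 1)
  pos <- open$mean_delta > 0
  expect_true(all(open$is_peak[pos]))

  # a single culture carries no variance estimate
  expect_error(call_hmc_peaks(delta[, 1, drop = FALSE]),
               class = "oxbspipe_validation_error")
})
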