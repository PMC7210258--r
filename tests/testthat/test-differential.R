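test_that("the per-probe group fit reproduces direct two-sample formulas", {
  vals <- rbind(p1 = c(0.6, 0.6, 0.4, 0.4),
                p2 = c(0.5, 0.5, 0.5, 0.5))
  design <- c("t", "t", "r", "r")
  fit <- fit_group_model(vals, design, c("t", "r"))
  expect_equal(fit$delta_beta, c(0.2, 0))
  expect_equal(fit$s2, c(0, 0))
  expect_equal(fit$df, c(2L, 2L))

  # hand-rolled comparison on random data with missingness
  set.seed(31)
  vals2 <- matrix(runif(50 * 8), 50, 8,
                  dimnames = list(sprintf("p%02d", 1:50), NULL))
  vals2[sample(length(vals2), 40)] <- NA
  design2 <- rep(c("a", "b"), each = 4)
  fit2 <- fit_group_model(vals2, design2, c("a", "b"))
  for (i in c(3, 17, 42)) {
    x <- vals2[i, design2 == "a"]; y <- vals2[i, design2 == "b"]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) >= 2 && length(y) >= 2) {
      expect_equal(fit2$delta_beta[i], mean(x) - mean(y), tolerance = 1e-12)
      s2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) /
        (length(x) + length(y) - 2)
      expect_equal(fit2$s2[i], s2, tolerance = 1e-12)
    }
  }
  expect_error(fit_group_model(vals2, design2, c("a", "zzz")),
               class = "oxbspipe_design_error")
})

test_that("variance moderation has the classical t and complete-shrinkage limits", {
  set.seed(17)
  n <- 200
  vals <- matrix(rnorm(n * 6, 0.5, 0.05), n, 6,
                 dimnames = list(sprintf("p%03d", 1:n), NULL))
  design <- rep(c("a", "b"), each = 3)
  fit <- fit_group_model(vals, design, c("a", "b"))

  # shrinkage off reproduces the ordinary two-sample t
  off <- moderate_ebayes(fit, prior_df = 0)
  for (i in c(1, 50, 200)) {
    tt <- t.test(vals[i, 1:3], vals[i, 4:6], var.equal = TRUE)
    expect_equal(off$t_mod[i], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(off$p[i], tt$p.value, tolerance = 1e-10)
  }

  # constant-variance ensemble sits at the complete-shrinkage fixed point
  fitc <- fit
  fitc$s2 <- rep(0.004, n)
  modc <- moderate_ebayes(fitc)
  expect_identical(attr(modc, "d0"), Inf)
  expect_equal(attr(modc, "s02"), 0.004, tolerance = 1e-12)
  expect_equal(modc$t_mod, fitc$delta_beta / sqrt(0.004 * (1/3 + 1/3)),
               tolerance = 1e-12)

  # the estimated prior agrees with the established moderated-t machinery,
  # on a genuinely heteroskedastic ensemble (finite prior df)
  sds <- exp(rnorm(n, log(0.05), 0.6))
  vals_h <- matrix(rnorm(n * 6, 0, rep(sds, 6)), n, 6,
                   dimnames = list(sprintf("p%03d", 1:n), NULL))
  fit <- fit_group_model(vals_h, design, c("a", "b"))
  mod <- moderate_ebayes(fit)
  expect_true(is.finite(attr(mod, "d0")))
  sq <- limma::squeezeVar(fit$s2, df = fit$df)
  expect_equal(attr(mod, "d0"), sq$df.prior, tolerance = 1e-6)
  expect_equal(attr(mod, "s02"), sq$var.prior, tolerance = 1e-6)
  s2_post <- (fit$delta_beta / (mod$t_mod * fit$stdev_unscaled))^2
  expect_equal(s2_post, sq$var.post, tolerance = 1e-6)

  # degenerate ensembles are rejected with guidance
  fit0 <- fit; fit0$s2 <- rep(0, n)
  expect_error(moderate_ebayes(fit0), regexp = "replicates")
  expect_error(moderate_ebayes(fit[1:5, ]), class = "oxbspipe_validation_error")
})

test_that("BH adjustment matches the hand oracle and is permutation-stable", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_bh(0.5), 0.5)
  expect_equal(adjust_bh(rep(1, 5)), rep(1, 5))
  expect_error(adjust_bh(c(0.2, 1.7)), class = "oxbspipe_validation_error")

  set.seed(5)
  for (rep in 1:5) {
    p <- runif(sample(5:40, 1))^2
    expect_equal(adjust_bh(p), bh_oracle(p), tolerance = 1e-12)
    perm <- sample(length(p))
    expect_equal(adjust_bh(p[perm]), adjust_bh(p)[perm], tolerance = 1e-12)
  }
  # monotone in each p-value
  p <- c(0.01, 0.2, 0.5)
  p2 <- c(0.02, 0.2, 0.5)
  expect_true(all(adjust_bh(p2) >= adjust_bh(p)))
})

test_that("position calls require both the FDR and the effect-size threshold", {
  diff <- data.frame(probe_id = c("a", "b", "c"),
                     delta_beta = c(0.25, 0.15, 0.25),
                     fdr = c(0.01, 0.001, 0.05))
  out <- call_positions(diff, delta_min = 0.20, alpha = 0.05)
  expect_identical(out$significant, c(TRUE, FALSE, FALSE))  # strict fdr < alpha
  # sign-blind magnitude rule
  diff$delta_beta <- -diff$delta_beta
  expect_identical(call_positions(diff)$significant, c(TRUE, FALSE, FALSE))
})

test_that("region calling clusters by proximity and combines members by Stouffer", {
  pos <- data.frame(chrom = "chr1",
                    pos = c(101L, 501L, 901L, 5001L, 9001L),
                    probe_id = sprintf("p%d", 1:5),
                    z = c(2, 2, 2, 3, 1),
                    delta_beta = 0.3,
                    significant = c(TRUE, TRUE, TRUE, TRUE, FALSE))
  reg <- call_regions(pos, maxgap = 1000, min_cpgs = 3)
  expect_equal(nrow(reg), 1L)
  expect_equal(reg$start, 100L)   # 0-based half-open span of member CpGs
  expect_equal(reg$end, 901L)
  expect_equal(reg$n_cpgs, 3L)
  expect_equal(reg$stouffer_z, 6 / sqrt(3), tolerance = 1e-12)
  expect_equal(reg$p, 2 * pnorm(-6 / sqrt(3)), tolerance = 1e-12)

  # two significant CpGs never form a region at min_cpgs = 3
  pos2 <- pos[1:2, ]
  expect_equal(nrow(call_regions(pos2)), 0L)

  # unsorted input is rejected
  expect_error(call_regions(pos[c(2, 1, 3, 4, 5), ]),
               class = "oxbspipe_validation_error")

  # regions are disjoint and cover every qualifying significant CpG
  set.seed(8)
  posr <- data.frame(chrom = "chr1", pos = sort(sample(1:50000, 200)),
                     z = rnorm(200, 2), delta_beta = 0.3,
                     significant = runif(200) < 0.5)
  posr$probe_id <- sprintf("q%03d", seq_len(nrow(posr)))
  regr <- call_regions(posr, maxgap = 500, min_cpgs = 3)
  if (nrow(regr) > 1) {
    o <- order(regr$start)
    expect_true(all(regr$start[o][-1] >= regr$end[o][-nrow(regr)]))
  }
  # reconstruct qualifying clusters independently and compare membership
  sig <- posr[posr$significant, ]
  cl <- cumsum(c(TRUE, diff(sig$pos) > 500))
  want <- unlist(lapply(split(sig$probe_id, cl),
                        function(x) if (length(x) >= 3) x else NULL))
  got <- unlist(strsplit(regr$probe_ids, ","))
  expect_setequal(got, want)
})

test_that("the rank-sum comparison is exact on small samples and symmetric", {
  r <- compare_groups_wilcoxon(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p, 0.1)   # 2/20 labelings are as extreme

  expect_warning(r0 <- compare_groups_wilcoxon(c(2, 2), c(2, 2)),
                 regexp = "identical")
  expect_equal(r0$p, 1)

  ri <- compare_groups_wilcoxon(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ri$p, 1)

  set.seed(12)
  for (rep in 1:10) {
    a <- round(runif(sample(3:6, 1)), 2)
    b <- round(runif(sample(3:6, 1)), 2)
    r1 <- compare_groups_wilcoxon(a, b)
    r2 <- compare_groups_wilcoxon(b, a)
    expect_equal(r1$p, r2$p, tolerance = 1e-12)
    if (!anyDuplicated(c(a, b)))
      expect_equal(r1$p, wilcoxon_enum_oracle(a, b), tolerance = 1e-9)
  }
})
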