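#' Per-probe two-group linear fit
#'
#' Ordinary least squares per probe for a two-group contrast: the effect is
#' the difference of group means (target minus reference), the residual
#' variance is pooled within groups, and degrees of freedom are counted
#' after per-probe NA removal. Probes with fewer than two non-missing
#' values in either group are flagged untestable and carried through
#' without statistics.
#'
#' @param values probes x samples numeric matrix (betas or 5hmC estimates).
#' @param design condition label per column of `values`.
#' @param contrast length-2 character vector `(target, reference)`.
#' @return data.frame of class `probe_fit`: probe_id, delta_beta, s2, df,
#'   stdev_unscaled (the SE factor sqrt(1/n1 + 1/n2)), testable.
#' @export
fit_group_model <- function(values, design, contrast) {
  if (length(design) != ncol(values))
    stop_ox("`design` must label every column of `values`",
            class = "oxbspipe_validation_error")
  if (length(contrast) != 2L || !all(contrast %in% design))
    stop_ox("contrast (%s) references unknown condition",
            paste(contrast, collapse = ":"), class = "oxbspipe_design_error")
  vt <- values[, design == contrast[1L], drop = FALSE]
  vr <- values[, design == contrast[2L], drop = FALSE]
  nt <- rowSums(!is.na(vt)); nr <- rowSums(!is.na(vr))
  mt <- rowMeans(vt, na.rm = TRUE); mr <- rowMeans(vr, na.rm = TRUE)
  sst <- rowSums((vt - mt)^2, na.rm = TRUE)
  ssr <- rowSums((vr - mr)^2, na.rm = TRUE)
  df <- nt + nr - 2L
  testable <- nt >= 2L & nr >= 2L
  out <- data.frame(probe_id = rownames(values),
                    delta_beta = mt - mr,
                    s2 = ifelse(df > 0L, (sst + ssr) / df, NA_real_),
                    df = df,
                    stdev_unscaled = sqrt(1 / nt + 1 / nr),
                    testable = testable, stringsAsFactors = FALSE)
  out$delta_beta[!testable] <- ifelse(nt[!testable] >= 1L & nr[!testable] >= 1L,
                                      out$delta_beta[!testable], NA_real_)
  class(out) <- c("probe_fit", "data.frame")
  out
}

# Newton inversion of the trigamma function (solves trigamma(x) = y);
# monotone decreasing and convex, so the iteration is globally stable
#' @noRd
.trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (abs(dif) / x < 1e-8) break
  }
  x
}

#' Moderated t-statistics via empirical-Bayes variance shrinkage
#'
#' Standard moderated-t construction: the per-probe residual variances are
#' modelled as scaled chi-square draws around a prior (d0, s0^2), estimated
#' by method of moments on log s^2 across the probe ensemble (trigamma
#' matching for d0, Newton inversion to 1e-8; d0 above 1e6 is treated as
#' infinite). The posterior variance `(d0*s0^2 + df*s2) / (d0 + df)`
#' replaces s2 in the t-statistic, which gains d0 extra degrees of freedom.
#' When the ensemble shows no excess dispersion beyond chi-square sampling
#' noise, shrinkage is complete: d0 = Inf and s0^2 is the mean of the
#' observed variances, so a constant-variance ensemble shrinks to exactly
#' that common value.
#'
#' @param fits a `probe_fit` from [fit_group_model()] (or any data.frame
#'   with delta_beta, s2, df, stdev_unscaled, testable).
#' @param prior_df optional override of d0: 0 switches shrinkage off
#'   (classical t), Inf forces complete shrinkage.
#' @return `fits` augmented with t_mod, p (two-sided), df_total; the prior
#'   is attached as attributes `d0` and `s02`.
#' @export
moderate_ebayes <- function(fits, prior_df = NULL) {
  ok <- fits$testable & !is.na(fits$s2)
  s2 <- fits$s2[ok]; df <- fits$df[ok]
  if (sum(ok) < 10L)
    stop_ox("moment estimation of the variance prior needs >= 10 testable probes",
            class = "oxbspipe_validation_error")
  if (all(s2 == 0))
    stop_ox("all residual variances are zero; more replicates (or jitter) needed",
            class = "oxbspipe_validation_error")
  # floor tiny variances at 1e-5 x median before the log-moment fit: count
  # discretization of betas produces near-zero sample variances whose logs
  # would otherwise dominate the dispersion estimate
  s2f <- pmax(s2, 1e-5 * stats::median(s2))
  e <- log(s2f) - digamma(df / 2) + log(df / 2)
  evar <- stats::var(e) - mean(trigamma(df / 2))
  if (is.null(prior_df)) {
    if (is.na(evar) || evar <= 0) {
      # no detectable excess dispersion: complete shrinkage to the mean
      # observed variance (unbiased for the common value)
      d0 <- Inf
      s02 <- mean(s2f)
    } else {
      d0 <- 2 * .trigamma_inverse(evar)
      if (d0 > 1e6) d0 <- Inf
      s02 <- if (is.finite(d0))
        exp(mean(e) + digamma(d0 / 2) - log(d0 / 2)) else mean(s2f)
    }
  } else {
    d0 <- prior_df
    s02 <- if (d0 == 0) NA_real_ else if (is.finite(d0))
      exp(mean(e) + digamma(d0 / 2) - log(d0 / 2)) else mean(s2f)
  }
  s2_tilde <- rep(NA_real_, nrow(fits))
  if (is.infinite(d0)) {
    s2_tilde[ok] <- s02
  } else if (d0 == 0) {
    s2_tilde[ok] <- fits$s2[ok]
  } else {
    s2_tilde[ok] <- (d0 * s02 + fits$df[ok] * fits$s2[ok]) / (d0 + fits$df[ok])
  }
  fits$df_total <- fits$df + d0
  fits$t_mod <- fits$delta_beta / (sqrt(s2_tilde) * fits$stdev_unscaled)
  fits$t_mod[!ok] <- NA_real_
  fits$p <- 2 * stats::pt(-abs(fits$t_mod), df = fits$df_total)
  attr(fits, "d0") <- d0
  attr(fits, "s02") <- s02
  fits
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment with monotonicity enforcement, stable under input
#' reordering. Thin validated wrapper over [stats::p.adjust].
#'
#' @param p probabilities in [0,1] (NA passed through).
#' @return Adjusted p-values in input order.
#' @export
adjust_bh <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop_ox("p-values must lie in [0,1]", class = "oxbspipe_validation_error")
  stats::p.adjust(p, method = "BH")
}

#' Threshold-based significance calls at positions
#'
#' A position is significant when its FDR is strictly below `alpha` and the
#' absolute effect reaches `delta_min` (default 20%, the magnitude filter
#' for differential calls; peak-stage calls use 10%).
#'
#' @param diff data.frame with delta_beta and fdr columns.
#' @param delta_min minimum |delta_beta|.
#' @param alpha FDR cutoff (strict).
#' @return `diff` with a logical `significant` column added.
#' @export
call_positions <- function(diff, delta_min = 0.20, alpha = 0.05) {
  if (is.null(diff$fdr))
    stop_ox("`diff` must carry an fdr column (run adjust_bh first)",
            class = "oxbspipe_validation_error")
  diff$significant <- !is.na(diff$fdr) & diff$fdr < alpha &
    !is.na(diff$delta_beta) & abs(diff$delta_beta) >= delta_min
  diff
}

#' Full position-level differential test
#'
#' Convenience composition: [fit_group_model()] then [moderate_ebayes()]
#' then BH over testable probes and [call_positions()]. Untestable probes
#' are excluded from the multiple-testing correction (not assigned p = 1)
#' and reported with NA statistics.
#'
#' @inheritParams fit_group_model
#' @inheritParams call_positions
#' @return data.frame: probe_id, delta_beta, s2, df, t_mod, p, fdr,
#'   significant.
#' @export
test_positions <- function(values, design, contrast, delta_min = 0.20,
                           alpha = 0.05) {
  fits <- fit_group_model(values, design, contrast)
  mod <- moderate_ebayes(fits)
  mod$fdr <- NA_real_
  mod$fdr[mod$testable] <- adjust_bh(mod$p[mod$testable])
  call_positions(mod, delta_min = delta_min, alpha = alpha)
}

#' Proximity-based region calling
#'
#' Clusters consecutive significant CpGs whose successive gaps are at most
#' `maxgap` bp and keeps clusters with at least `min_cpgs` members. Each
#' region is scored by the Stouffer combination `z = sum(z_i) / sqrt(k)` of
#' its member per-CpG z-scores, with a two-sided normal p and BH across
#' regions. The region span is the 0-based half-open interval from the
#' first member CpG to one past the last.
#'
#' @param positions data.frame sorted by (chrom, pos) with columns chrom,
#'   pos (1-based CpG position), significant, and either `z` or (`p`,
#'   `delta_beta`) from which a signed z is derived.
#' @param maxgap maximum gap between successive member CpGs (bp).
#' @param min_cpgs minimum CpGs per region.
#' @return data.frame of regions: chrom, start, end, n_cpgs, probe_ids
#'   (comma-joined), mean_delta, stouffer_z, p, fdr.
#' @export
call_regions <- function(positions, maxgap = 1000, min_cpgs = 3) {
  o <- order(positions$chrom, positions$pos)
  if (!identical(o, seq_len(nrow(positions))))
    stop_ox("`positions` must be sorted by (chrom, pos)",
            class = "oxbspipe_validation_error")
  if (is.null(positions$z)) {
    if (is.null(positions$p) || is.null(positions$delta_beta))
      stop_ox("`positions` needs a z column, or p plus delta_beta",
              class = "oxbspipe_validation_error")
    # signed z from the two-sided p: quantile of the matching one-sided tail
    positions$z <- sign(positions$delta_beta) *
      stats::qnorm(pmax(positions$p, 1e-300) / 2, lower.tail = FALSE)
  }
  sig <- positions[which(positions$significant), , drop = FALSE]
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_cpgs = integer(0),
                      probe_ids = character(0), mean_delta = numeric(0),
                      stouffer_z = numeric(0), p = numeric(0),
                      fdr = numeric(0), stringsAsFactors = FALSE)
  if (nrow(sig) == 0L) return(empty)
  new_cluster <- c(TRUE, diff(sig$pos) > maxgap | sig$chrom[-1L] != sig$chrom[-nrow(sig)])
  cl <- cumsum(new_cluster)
  regions <- do.call(rbind, lapply(split(sig, cl), function(s) {
    if (nrow(s) < min_cpgs) return(NULL)
    z <- sum(s$z) / sqrt(nrow(s))
    data.frame(chrom = s$chrom[1L], start = min(s$pos) - 1L, end = max(s$pos),
               n_cpgs = nrow(s),
               probe_ids = paste(s$probe_id %||% rownames(s), collapse = ","),
               mean_delta = if (is.null(s$delta_beta)) NA_real_ else
                 mean(s$delta_beta),
               stouffer_z = z, p = 2 * stats::pnorm(-abs(z)),
               stringsAsFactors = FALSE)
  }))
  if (is.null(regions)) return(empty)
  regions$fdr <- adjust_bh(regions$p)
  rownames(regions) <- NULL
  regions
}

#' Two-sided Mann-Whitney/Wilcoxon rank-sum comparison
#'
#' Exact enumeration when the pooled sample size is at most 12 and no ties
#' are present; otherwise the normal approximation with tie correction
#' (no continuity correction, so identical groups give p = 1 exactly).
#'
#' @param values_a,values_b non-empty numeric vectors.
#' @return list with `U` (rank-sum statistic of the first group) and `p`.
#' @export
compare_groups_wilcoxon <- function(values_a, values_b) {
  if (length(values_a) == 0L || length(values_b) == 0L)
    stop_ox("both groups must be non-empty", class = "oxbspipe_validation_error")
  pooled <- c(values_a, values_b)
  if (length(unique(pooled)) == 1L) {
    warning("all values identical across both groups; p = 1")
    return(list(U = length(values_a) * length(values_b) / 2, p = 1))
  }
  ties <- anyDuplicated(pooled) > 0L
  use_exact <- length(pooled) <= 12L && !ties
  w <- suppressWarnings(
    stats::wilcox.test(values_a, values_b, exact = use_exact,
                       correct = FALSE))
  list(U = unname(w$statistic), p = w$p.value)
}
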