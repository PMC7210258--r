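# pair BS and oxBS samples by (condition, culture); returns a data.frame
# with one row per pair
#' @noRd
pair_samples <- function(design, bs, oxbs) {
  validate_design(design, bs, oxbs)
  b <- design[design$channel == "BS", ]
  o <- design[design$channel == "oxBS", ]
  key <- paste(b$condition, b$culture)
  m <- match(key, paste(o$condition, o$culture))
  data.frame(pair_id = b$culture, condition = b$condition,
             bs_sample = b$sample_id, ox_sample = o$sample_id[m],
             stringsAsFactors = FALSE)
}

#' Naive paired BS minus oxBS signal
#'
#' The first-pass hydroxymethylation signal: per probe and culture, the BS
#' beta minus the oxBS beta of the paired sample. Negative values are
#' retained at this stage (the NA convention belongs to the MLE step).
#'
#' @param bs,oxbs paired `beta_matrix` objects.
#' @param design sample sheet pairing the channels by (condition, culture).
#' @return Matrix probes x cultures of deltas in [-1, 1], with the pairing
#'   table attached as attribute `pairs`.
#' @export
naive_delta <- function(bs, oxbs, design) {
  pairs <- pair_samples(design, bs, oxbs)
  if (anyNA(pairs$ox_sample))
    stop_ox("unpaired culture: %s", pairs$pair_id[is.na(pairs$ox_sample)][1L],
            class = "oxbspipe_pairing_error")
  d <- bs$beta[, pairs$bs_sample, drop = FALSE] -
    oxbs$beta[, pairs$ox_sample, drop = FALSE]
  colnames(d) <- pairs$pair_id
  attr(d, "pairs") <- pairs
  d
}

#' Binomial maximum-likelihood estimate of (5mC, 5hmC) at one CpG
#'
#' Model: `x_bs ~ Binomial(n_bs, m + h)` and `x_ox ~ Binomial(n_ox, m)`
#' with counts recovered from betas as `x = round(beta * n)`, maximizing the
#' joint log-likelihood under `m >= 0, h >= 0, m + h <= 1`. When the BS
#' count fraction is at least the oxBS count fraction the interior solution
#' applies: `m_hat` is the oxBS fraction and `h_hat` their difference.
#' Otherwise the optimum sits on the `h = 0` boundary: `h_hat` is reported
#' as NA (the convention for negative 5hmC) and `m_hat` is the pooled count
#' fraction `(x_bs + x_ox) / (n_bs + n_ox)`, which remains a meaningful 5mC
#' estimate. Ties (`equal fractions`) take the interior solution `h = 0`.
#'
#' All arguments are vectorized.
#'
#' @param beta_bs,beta_ox betas in [0,1].
#' @param n_bs,n_ox pseudo-coverages (>= 1).
#' @return list with numeric vectors `m_hat` and `h_hat` (NA where the 5hmC
#'   estimate is undefined).
#' @export
oxbs_mle <- function(beta_bs, n_bs, beta_ox, n_ox) {
  if (any(c(n_bs, n_ox) < 1, na.rm = TRUE))
    stop_ox("coverage must be >= 1", class = "oxbspipe_validation_error")
  if (any(c(beta_bs, beta_ox) < 0 | c(beta_bs, beta_ox) > 1, na.rm = TRUE))
    stop_ox("betas must lie in [0,1]", class = "oxbspipe_validation_error")
  x_bs <- round(beta_bs * n_bs); x_ox <- round(beta_ox * n_ox)
  p_bs <- x_bs / n_bs; p_ox <- x_ox / n_ox
  interior <- p_bs >= p_ox
  m_hat <- ifelse(interior, p_ox, (x_bs + x_ox) / (n_bs + n_ox))
  h_hat <- ifelse(interior, p_bs - p_ox, NA_real_)
  miss <- is.na(beta_bs) | is.na(beta_ox)
  m_hat[miss] <- NA_real_; h_hat[miss] <- NA_real_
  list(m_hat = m_hat, h_hat = h_hat)
}

#' Per-CpG methylome estimation over all cultures
#'
#' Applies [oxbs_mle()] to every probe x culture pair and assembles the 5mC
#' and 5hmC estimate matrices with the NA mask (true where the 5hmC
#' estimate is undefined because the BS beta fell below the paired oxBS
#' beta). The per-culture NA fraction is reported via `message()`.
#'
#' @param bs,oxbs paired, QC-filtered `beta_matrix` objects.
#' @param design sample sheet.
#' @param quiet suppress the NA-fraction log line.
#' @return Object of class `methylome_estimate`: matrices `m`, `h`,
#'   `na_mask` (probes x cultures), `pairs`, `probes`.
#' @export
estimate_methylome <- function(bs, oxbs, design, quiet = FALSE) {
  pairs <- pair_samples(design, bs, oxbs)
  n <- nrow(bs$beta)
  m <- h <- matrix(NA_real_, n, nrow(pairs),
                   dimnames = list(bs$probes$probe_id, pairs$pair_id))
  for (j in seq_len(nrow(pairs))) {
    est <- oxbs_mle(bs$beta[, pairs$bs_sample[j]],
                    bs$coverage[, pairs$bs_sample[j]],
                    oxbs$beta[, pairs$ox_sample[j]],
                    oxbs$coverage[, pairs$ox_sample[j]])
    m[, j] <- est$m_hat; h[, j] <- est$h_hat
  }
  na_mask <- is.na(h) & !is.na(m)
  if (!quiet)
    message("5hmC NA fraction per culture: ",
            paste(sprintf("%s=%.2f", pairs$pair_id, colMeans(na_mask)),
                  collapse = ", "))
  structure(list(m = m, h = h, na_mask = na_mask, pairs = pairs,
                 probes = bs$probes),
            class = "methylome_estimate")
}

#' @export
print.methylome_estimate <- function(x, ...) {
  cat("methylome_estimate:", nrow(x$m), "probes x", ncol(x$m), "cultures\n")
  cat(sprintf("  overall 5hmC NA fraction: %.3f\n", mean(x$na_mask)))
  invisible(x)
}

#' Global 5hmC as proportional signal loss after oxidation
#'
#' Estimates global hydroxymethylation per condition as
#' `1 - mean(beta_oxBS) / mean(beta_BS)` over a probe scope: the fraction
#' of total methylation signal lost upon oxidation. When a second BS
#' matrix is supplied the same quantity is computed BS-vs-BS as the
#' technical-replicate baseline of the assay.
#'
#' @param bs,oxbs paired `beta_matrix` objects.
#' @param design sample sheet.
#' @param scope probe ids to average over (default: all probes).
#' @param bs_replicate optional second BS `beta_matrix` for the
#'   technical-replicate analogue.
#' @return data.frame with condition, signal loss, and (when requested)
#'   the BS-vs-BS baseline column `loss_bs_technical`.
#' @export
global_hmc_loss <- function(bs, oxbs, design, scope = NULL,
                            bs_replicate = NULL) {
  scope <- scope %||% bs$probes$probe_id
  if (length(scope) == 0L)
    stop_ox("empty probe scope", class = "oxbspipe_validation_error")
  idx <- match(scope, bs$probes$probe_id)
  if (anyNA(idx))
    stop_ox("scope contains unknown probe ids", class = "oxbspipe_validation_error")
  conds <- unique(design$condition)
  one <- function(mat_num, mat_den, samples_num, samples_den) {
    den <- mean(mat_den[idx, samples_den, drop = FALSE], na.rm = TRUE)
    if (!is.finite(den) || den == 0)
      stop_ox("mean BS signal is zero over the scope; loss undefined",
              class = "oxbspipe_validation_error")
    1 - mean(mat_num[idx, samples_num, drop = FALSE], na.rm = TRUE) / den
  }
  out <- data.frame(condition = conds, loss = NA_real_)
  for (k in seq_along(conds)) {
    sb <- design$sample_id[design$condition == conds[k] & design$channel == "BS"]
    so <- design$sample_id[design$condition == conds[k] & design$channel == "oxBS"]
    out$loss[k] <- one(oxbs$beta, bs$beta, so, sb)
  }
  if (!is.null(bs_replicate)) {
    out$loss_bs_technical <- NA_real_
    for (k in seq_along(conds)) {
      sb <- design$sample_id[design$condition == conds[k] & design$channel == "BS"]
      out$loss_bs_technical[k] <- one(bs_replicate$beta, bs$beta, sb, sb)
    }
  }
  out
}

#' Call 5hmC presence peaks
#'
#' A peak is a CpG whose mean paired BS - oxBS difference across cultures
#' is significantly positive (one-sided moderated t against zero, BH over
#' probes) and at least `min_delta` (default 10%, the sensitivity floor of
#' the paired-array technique).
#'
#' @param delta probes x cultures delta matrix from [naive_delta()].
#' @param design sample sheet (or NULL if `delta` carries its `pairs`
#'   attribute).
#' @param condition condition to test; NULL pools all cultures in `delta`.
#' @param min_delta minimum mean delta for a peak (default 0.10).
#' @param alpha FDR cutoff (default 0.05).
#' @return data.frame of `PeakCall` rows: probe_id, condition, mean_delta,
#'   t_mod, p (one-sided), fdr, is_peak.
#' @export
call_hmc_peaks <- function(delta, design = NULL, condition = NULL,
                           min_delta = 0.10, alpha = 0.05) {
  pairs <- attr(delta, "pairs")
  if (!is.null(condition)) {
    if (is.null(pairs))
      stop_ox("`delta` lacks pairing metadata; pass the naive_delta output",
              class = "oxbspipe_validation_error")
    delta <- delta[, pairs$pair_id[pairs$condition == condition], drop = FALSE]
  }
  if (ncol(delta) < 2L)
    stop_ox("peak calling needs >= 2 cultures (no variance estimate otherwise)",
            class = "oxbspipe_validation_error")
  nn <- rowSums(!is.na(delta))
  mean_d <- rowMeans(delta, na.rm = TRUE)
  s2 <- apply(delta, 1L, stats::var, na.rm = TRUE)
  fits <- data.frame(probe_id = rownames(delta), delta_beta = mean_d,
                     s2 = s2, df = nn - 1L, stdev_unscaled = sqrt(1 / nn),
                     testable = nn >= 2L, stringsAsFactors = FALSE)
  mod <- moderate_ebayes(fits)
  tested <- mod[mod$testable, , drop = FALSE]
  # one-sided: gain of 5hmC means signal loss after oxidation, delta > 0
  p1 <- stats::pt(tested$t_mod, df = tested$df_total, lower.tail = FALSE)
  fdr <- adjust_bh(p1)
  out <- data.frame(probe_id = tested$probe_id,
                    condition = condition %||% NA_character_,
                    mean_delta = tested$delta_beta, t_mod = tested$t_mod,
                    p = p1, fdr = fdr,
                    is_peak = fdr < alpha & tested$delta_beta >= min_delta,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
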