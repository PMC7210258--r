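#' Construct a beta-value matrix for one conversion channel
#'
#' Container for one array channel (BS or oxBS): beta values, detection
#' p-values and binomial pseudo-coverage, all probes x samples, plus the
#' probe index. Probe positions are 1-based coordinates of the CpG cytosine.
#'
#' @param beta numeric matrix in [0,1] (NA allowed), rownames = probe_ids.
#' @param detection_p numeric matrix in [0,1], same shape.
#' @param coverage numeric matrix (>= 1) or a scalar recycled to all cells.
#' @param probes data.frame with columns probe_id, chrom, pos.
#' @param channel "BS" or "oxBS".
#' @return An object of class `beta_matrix`.
#' @export
beta_matrix <- function(beta, detection_p, coverage, probes, channel) {
  channel <- match.arg(channel, c("BS", "oxBS"))
  if (is.null(rownames(beta))) rownames(beta) <- probes$probe_id
  if (length(coverage) == 1L)
    coverage <- matrix(coverage, nrow(beta), ncol(beta),
                       dimnames = dimnames(beta))
  bm <- structure(list(beta = beta, detection_p = detection_p,
                       coverage = coverage, probes = probes,
                       channel = channel),
                  class = "beta_matrix")
  validate_beta_matrix(bm)
  bm
}

#' @noRd
validate_beta_matrix <- function(bm, source = "beta_matrix") {
  b <- bm$beta
  if (anyDuplicated(bm$probes$probe_id))
    stop_ox("%s: duplicate probe_ids", source, class = "oxbspipe_format_error")
  if (!identical(rownames(b), bm$probes$probe_id))
    stop_ox("%s: beta rownames must equal the probe index", source,
            class = "oxbspipe_alignment_error")
  bad <- which(!is.na(b) & (b < 0 | b > 1), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop_ox("%s: beta value %.4g outside [0,1] at probe %s, sample %s",
            source, b[bad[1L, 1L], bad[1L, 2L]],
            rownames(b)[bad[1L, 1L]], colnames(b)[bad[1L, 2L]],
            class = "oxbspipe_format_error")
  dp <- bm$detection_p
  badp <- which(!is.na(dp) & (dp < 0 | dp > 1), arr.ind = TRUE)
  if (nrow(badp) > 0L)
    stop_ox("%s: detection p outside [0,1] at probe %s, sample %s", source,
            rownames(dp)[badp[1L, 1L]], colnames(dp)[badp[1L, 2L]],
            class = "oxbspipe_format_error")
  if (!identical(dim(dp), dim(b)) || !identical(dim(bm$coverage), dim(b)))
    stop_ox("%s: beta/detection_p/coverage dimensions differ", source,
            class = "oxbspipe_alignment_error")
  if (any(bm$coverage < 1, na.rm = TRUE))
    stop_ox("%s: coverage must be >= 1", source,
            class = "oxbspipe_validation_error")
  invisible(bm)
}

# probe subsetting, keeping all three matrices and the index aligned
#' @export
`[.beta_matrix` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$probes$probe_id)
  x$beta <- x$beta[i, , drop = FALSE]
  x$detection_p <- x$detection_p[i, , drop = FALSE]
  x$coverage <- x$coverage[i, , drop = FALSE]
  x$probes <- x$probes[i, , drop = FALSE]
  x
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat(sprintf("beta_matrix (%s): %d probes x %d samples\n", x$channel,
              nrow(x$beta), ncol(x$beta)))
  cat("  samples:", paste(utils::head(colnames(x$beta), 6L), collapse = ", "),
      if (ncol(x$beta) > 6L) "...", "\n")
  invisible(x)
}

#' Simulate paired BS/oxBS arrays from a ground-truth methylome
#'
#' Measurement model: for each culture replicate and probe, the BS channel
#' draws `x_bs ~ Binomial(N, m + h)` and the oxBS channel
#' `x_ox ~ Binomial(N, m)` at pseudo-coverage N, and reports betas as
#' count fractions. A planted subpopulation of failure-prone probes
#' (`bad_probe_frac`, per-cell failure rate `bad_probe_fail_rate`) plus a
#' low background failure rate generate detection p-values exceeding 0.01,
#' giving the detection-based probe filter real targets. Paired BS/oxBS
#' samples share the culture identifier.
#'
#' @param truth a `truth_methylome`.
#' @param config the [sim_config()] used to generate it.
#' @return A list of class `paired_arrays`: `bs` and `oxbs` (`beta_matrix`),
#'   `samples` (sample sheet: sample_id, culture, condition, channel) and
#'   `bad_probes` (planted failure-prone probe ids).
#' @export
simulate_paired_arrays <- function(truth, config) {
  if (!inherits(truth, "truth_methylome"))
    stop_ox("`truth` must be a truth_methylome", class = "oxbspipe_validation_error")
  if (!identical(sort(truth$conditions), sort(config$conditions)))
    stop_ox("truth/config condition mismatch", class = "oxbspipe_validation_error")
  set.seed(config$seed + 2L)
  N <- config$coverage
  pr <- truth$probes
  n <- nrow(pr)

  sheet <- do.call(rbind, lapply(config$conditions, function(cc) {
    cultures <- sprintf("%s_c%d", cc, seq_len(config$replicates[[cc]]))
    data.frame(sample_id = c(paste0(cultures, "_BS"), paste0(cultures, "_oxBS")),
               culture = rep(cultures, 2L), condition = cc,
               channel = rep(c("BS", "oxBS"), each = length(cultures)),
               stringsAsFactors = FALSE)
  }))

  # failure-prone probes are drawn outside the planted differential blocks,
  # which exist as ground truth for the region caller, not the QC stage
  eligible <- pr$probe_id[is.na(pr$block_id %||% rep(NA, n))]
  bad <- sort(sample(eligible, round(config$bad_probe_frac * n)))
  fail_rate <- ifelse(pr$probe_id %in% bad, config$bad_probe_fail_rate,
                      config$detection_fail_rate)

  draw_channel <- function(channel) {
    sub <- sheet[sheet$channel == channel, , drop = FALSE]
    beta <- dp <- matrix(NA_real_, n, nrow(sub),
                         dimnames = list(pr$probe_id, sub$sample_id))
    for (j in seq_len(nrow(sub))) {
      cc <- sub$condition[j]
      p <- if (channel == "BS") pmin(1, truth$m[, cc] + truth$h[, cc]) else
        truth$m[, cc]
      beta[, j] <- stats::rbinom(n, N, p) / N
      fails <- stats::runif(n) < fail_rate
      dp[, j] <- ifelse(fails, stats::runif(n, 0.011, 1),
                        stats::runif(n, 0, 0.01))
    }
    beta_matrix(beta, dp, N, pr[c("probe_id", "chrom", "pos")], channel)
  }

  bs <- draw_channel("BS")
  oxbs <- draw_channel("oxBS")
  structure(list(bs = bs, oxbs = oxbs, samples = sheet, bad_probes = bad),
            class = "paired_arrays")
}

#' @export
print.paired_arrays <- function(x, ...) {
  cat("paired_arrays:", nrow(x$bs$beta), "probes,",
      nrow(x$samples), "samples (",
      sum(x$samples$channel == "BS"), "BS +",
      sum(x$samples$channel == "oxBS"), "oxBS ),",
      length(x$bad_probes), "planted failure-prone probes\n")
  invisible(x)
}

#' Validate a sample sheet against paired matrices
#'
#' Checks that every (condition, culture) has exactly one BS and one oxBS
#' sample and that sample ids match the matrix columns.
#' @param sheet sample sheet data.frame.
#' @param bs,oxbs `beta_matrix` objects.
#' @return The sheet, invisibly; errors on violation.
#' @export
validate_design <- function(sheet, bs, oxbs) {
  need <- c("sample_id", "culture", "condition", "channel")
  if (!all(need %in% names(sheet)))
    stop_ox("sample sheet must have columns %s", paste(need, collapse = ", "),
            class = "oxbspipe_validation_error")
  tab <- table(paste(sheet$condition, sheet$culture), sheet$channel)
  if (!all(tab == 1L) || !all(c("BS", "oxBS") %in% colnames(tab)))
    stop_ox("each (condition, culture) needs exactly one BS and one oxBS sample",
            class = "oxbspipe_pairing_error")
  if (!setequal(sheet$sample_id[sheet$channel == "BS"], colnames(bs$beta)) ||
      !setequal(sheet$sample_id[sheet$channel == "oxBS"], colnames(oxbs$beta)))
    stop_ox("sample sheet does not match matrix columns",
            class = "oxbspipe_alignment_error")
  invisible(sheet)
}
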