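#' Detection-based probe filtering
#'
#' Removes low-quality probes: pooling all BS and oxBS samples into one
#' panel, a probe is dropped from both matrices when its detection p-value
#' exceeds `detp_threshold` in strictly more than `sample_frac` of the
#' samples. The boundary is exclusive ("more than"), so a probe failing in
#' exactly 10% of samples is kept at the defaults.
#'
#' @param bs,oxbs paired `beta_matrix` objects sharing a probe index.
#' @param detp_threshold detection p-value cutoff (default 0.01).
#' @param sample_frac failing-sample fraction above which a probe is
#'   removed (default 0.10).
#' @return list with filtered `bs`, `oxbs`, and `report` (data.frame of
#'   removed probes with failing counts).
#' @export
filter_probes <- function(bs, oxbs, detp_threshold = 0.01, sample_frac = 0.10) {
  if (!identical(bs$probes$probe_id, oxbs$probes$probe_id))
    stop_ox("BS and oxBS matrices must share a probe index",
            class = "oxbspipe_alignment_error")
  for (v in c(detp_threshold, sample_frac))
    if (v <= 0 || v >= 1)
      stop_ox("thresholds must lie in (0,1)", class = "oxbspipe_validation_error")
  dp <- cbind(bs$detection_p, oxbs$detection_p)
  n_fail <- rowSums(dp > detp_threshold, na.rm = TRUE)
  remove <- n_fail > sample_frac * ncol(dp)
  if (all(remove))
    stop_ox("empty after QC: every probe exceeded the detection threshold",
            class = "oxbspipe_qc_error")
  report <- data.frame(probe_id = bs$probes$probe_id[remove],
                       n_fail = unname(n_fail[remove]),
                       n_samples = rep(ncol(dp), sum(remove)),
                       stringsAsFactors = FALSE)
  list(bs = bs[!remove], oxbs = oxbs[!remove], report = report)
}

#' Stratified quantile normalization of beta values
#'
#' Within each probe stratum, maps every sample's beta values onto the
#' across-sample mean quantile function (via [limma::normalizeQuantiles]),
#' preserving within-sample ranks inside the stratum. This is the
#' normalization slot of the pipeline; it is off by default in
#' [run_pipeline()] because binomially simulated channels need none, and it
#' is a deliberate, documented stand-in for chemistry-aware within-array
#' normalization of real Infinium data, which needs probe-type information
#' this data model does not carry.
#'
#' @param bm a `beta_matrix` with >= 2 samples.
#' @param strata optional factor/vector over probes partitioning the probe
#'   set; NULL = one stratum. Strata with < 2 probes are left unnormalized
#'   with a warning.
#' @return The normalized `beta_matrix`.
#' @export
normalize_stratified_quantile <- function(bm, strata = NULL) {
  if (ncol(bm$beta) < 2L)
    stop_ox("quantile normalization needs >= 2 samples",
            class = "oxbspipe_validation_error")
  if (is.null(strata)) strata <- rep("all", nrow(bm$beta))
  if (length(strata) != nrow(bm$beta))
    stop_ox("`strata` must have one entry per probe",
            class = "oxbspipe_validation_error")
  for (s in unique(strata)) {
    idx <- which(strata == s)
    if (length(idx) < 2L) {
      warning(sprintf("stratum '%s' has < 2 probes; left unnormalized", s))
      next
    }
    bm$beta[idx, ] <- limma::normalizeQuantiles(bm$beta[idx, , drop = FALSE],
                                                ties = TRUE)
  }
  bm$beta[] <- pmin(pmax(bm$beta, 0), 1)
  validate_beta_matrix(bm, "normalize_stratified_quantile")
  bm
}
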