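#' Simulation configuration for the paired-array generator
#'
#' Bundles every tunable of the synthetic dataset: the seed, the binomial
#' pseudo-coverage standing in for array intensity, the replicate design,
#' the per-condition gene-body targets for true 5mC/5hmC, probe layout and
#' the detection-failure model. Defaults reproduce the hepatic progenitor
#' study design: pseudo-coverage 1000, cultures 2/2/3 for
#' proliferative/differentiating/ifc, gene-body mean 5hmC targets
#' 2.2/4.1/3.5 percent and 5mC targets 51.7/49.1/50.5 percent.
#'
#' @param seed integer seed; all generator randomness derives from it.
#' @param coverage binomial pseudo-coverage per probe x sample (reads-worth
#'   of evidence each beta value represents). Must be >= 1.
#' @param replicates named integer vector: cultures per condition (each >= 2).
#' @param h_body named numeric: per-condition target mean of true 5hmC over
#'   gene-body probes (fractions).
#' @param m_body named numeric: per-condition target mean of true 5mC over
#'   gene-body probes (fractions).
#' @param probes_per_body,probes_per_promoter,probes_per_cgi probe layout.
#' @param intergenic_spacing bp between intergenic backbone probes.
#' @param precision_h,precision_m beta-distribution precision (a+b) of
#'   per-probe truth around its regional mean; larger is less dispersed.
#' @param promoter_h_frac,cgi_h_frac,intergenic_h_frac regional 5hmC means
#'   for promoter/CGI/intergenic probes, as fractions of the condition's
#'   gene-body target (promoters and islands are 5hmC-depleted).
#' @param detection_fail_rate per-cell Bernoulli probability that a good
#'   probe's detection p-value exceeds 0.01.
#' @param bad_probe_frac fraction of probes planted as "bad" (failure-prone).
#' @param bad_probe_fail_rate per-cell failure probability for bad probes.
#' @param gs_weights_h list of named numeric vectors (per condition) scaling
#'   the gene-body 5hmC mean by gene-set label, before calibration; encodes
#'   the concentration of 5hmC gain on upregulated gene bodies.
#' @param intron_weight,exon_weight within-body 5hmC weights (introns are
#'   5hmC-enriched relative to exons).
#' @param body_span_max maximal span (bp) over which a gene's body probes
#'   are laid out, emulating the 5'-biased probe density of real arrays and
#'   keeping within-gene probe spacing below typical region-calling gaps.
#' @param n_planted_blocks number of gene-body blocks carrying a strong
#'   planted hydroxymethylation gain (ground truth for differential and
#'   region calling). Blocks are placed on consecutive body probes of
#'   upregulated genes.
#' @param block_size consecutive probes per planted block.
#' @param block_delta true 5hmC gain of block probes in `block_conditions`
#'   over the baseline (first) condition.
#' @param block_baseline_h baseline-condition true 5hmC at block probes;
#'   set above the measurement-noise floor so the paired MLE is defined in
#'   both groups and the blocks are genuinely testable.
#' @param block_conditions conditions receiving the planted gain; the
#'   default (differentiating only) encodes a differentiation-specific gain
#'   that the adenosine-derivative treatment reverts.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       coverage = 1000L,
                       replicates = c(proliferative = 2L, differentiating = 2L,
                                      ifc = 3L),
                       h_body = c(proliferative = 0.022, differentiating = 0.041,
                                  ifc = 0.035),
                       m_body = c(proliferative = 0.517, differentiating = 0.491,
                                  ifc = 0.505),
                       probes_per_body = 10L,
                       probes_per_promoter = 2L,
                       probes_per_cgi = 1L,
                       intergenic_spacing = 50000L,
                       precision_h = 1500,
                       precision_m = 150,
                       promoter_h_frac = 0.18,
                       cgi_h_frac = 0.10,
                       intergenic_h_frac = 0.45,
                       detection_fail_rate = 0.005,
                       bad_probe_frac = 0.05,
                       bad_probe_fail_rate = 0.5,
                       gs_weights_h = list(
                         proliferative  = c(up = 1.0, down = 1.0,
                                            housekeeping = 1.0, none = 1.0),
                         differentiating = c(up = 1.8, down = 0.75,
                                             housekeeping = 0.85, none = 1.0),
                         ifc            = c(up = 1.5, down = 0.8,
                                            housekeeping = 0.9, none = 1.0)),
                       intron_weight = 1.15,
                       exon_weight = 0.75,
                       body_span_max = 8000L,
                       n_planted_blocks = 4L,
                       block_size = 3L,
                       block_delta = 0.25,
                       block_baseline_h = 0.06,
                       block_conditions = "differentiating") {
  assert_scalar_number(seed, "seed")
  assert_scalar_number(coverage, "coverage", lower = 1)
  if (is.null(names(replicates)) || any(replicates < 2L))
    stop_ox("`replicates` must be a named vector with >= 2 cultures per condition",
            class = "oxbspipe_validation_error")
  conds <- names(replicates)
  if (!setequal(conds, names(h_body)) || !setequal(conds, names(m_body)))
    stop_ox("condition names of `replicates`, `h_body` and `m_body` must agree",
            class = "oxbspipe_validation_error")
  if (any(h_body < 0) || any(m_body < 0) || any(h_body + m_body[conds] > 1))
    stop_ox("infeasible condition profile: need 0 <= m + h <= 1 per condition",
            class = "oxbspipe_validation_error")
  for (r in c(detection_fail_rate, bad_probe_fail_rate))
    if (r < 0 || r >= 1)
      stop_ox("failure rates must lie in [0, 1)", class = "oxbspipe_validation_error")
  cfg <- list(seed = as.integer(seed), coverage = as.integer(coverage),
              replicates = replicates, conditions = conds,
              h_body = h_body[conds], m_body = m_body[conds],
              probes_per_body = probes_per_body,
              probes_per_promoter = probes_per_promoter,
              probes_per_cgi = probes_per_cgi,
              intergenic_spacing = intergenic_spacing,
              precision_h = precision_h, precision_m = precision_m,
              promoter_h_frac = promoter_h_frac, cgi_h_frac = cgi_h_frac,
              intergenic_h_frac = intergenic_h_frac,
              detection_fail_rate = detection_fail_rate,
              bad_probe_frac = bad_probe_frac,
              bad_probe_fail_rate = bad_probe_fail_rate,
              gs_weights_h = gs_weights_h,
              intron_weight = intron_weight, exon_weight = exon_weight,
              body_span_max = body_span_max,
              n_planted_blocks = as.integer(n_planted_blocks),
              block_size = as.integer(block_size),
              block_delta = block_delta,
              block_baseline_h = block_baseline_h,
              block_conditions = intersect(block_conditions, conds))
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config: seed", x$seed, "| pseudo-coverage", x$coverage, "\n")
  cat("  cultures:", paste(sprintf("%s=%d", names(x$replicates), x$replicates),
                           collapse = ", "), "\n")
  cat("  gene-body 5hmC targets:",
      paste(sprintf("%s=%.3f", names(x$h_body), x$h_body), collapse = ", "), "\n")
  cat("  gene-body 5mC targets: ",
      paste(sprintf("%s=%.3f", names(x$m_body), x$m_body), collapse = ", "), "\n")
  invisible(x)
}
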