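#' Relative expression by the delta-delta-Ct method
#'
#' `2^-(ddCt)` with `dCt = mean(Ct_gene) - mean(Ct_housekeeping)` and
#' `ddCt = dCt - control_mean_dct`; amplification efficiency is fixed at 2
#' as in the printed formula.
#'
#' @param ct_gene threshold cycles of the evaluated gene (>= 1 replicate).
#' @param ct_housekeeping threshold cycles of the housekeeping gene.
#' @param control_mean_dct mean dCt of the control condition (cycles).
#' @return Fold change relative to the control condition.
#' @export
relative_expression_ddct <- function(ct_gene, ct_housekeeping,
                                     control_mean_dct) {
  if (length(ct_gene) == 0L || length(ct_housekeeping) == 0L)
    stop_ox("at least one Ct replicate per role is required",
            class = "oxbspipe_validation_error")
  if (!all(is.finite(c(ct_gene, ct_housekeeping, control_mean_dct))))
    stop_ox("Ct values must be finite", class = "oxbspipe_validation_error")
  dct <- mean(ct_gene) - mean(ct_housekeeping)
  2^-(dct - control_mean_dct)
}

#' hMeDIP enrichment as percent of total input
#'
#' `2^((Ct_input10 - f) - Ct_IP) * 100`, where the compensatory factor `f`
#' accounts for the input dilution; the default 3.32 is the printed
#' rounding of log2(10) for a 1:10 input. [dilution_factor()] gives the
#' exact factor for any dilution. Strictly decreasing in `ct_ip`, and
#' invariant to adding a common offset to both Ct values.
#'
#' @param ct_ip threshold cycle of the immunoprecipitated DNA.
#' @param ct_input10 threshold cycle of the diluted (10%) input.
#' @param dilution_factor compensatory factor in cycles (default 3.32).
#' @return Percent of total input.
#' @export
hmedip_percent_input <- function(ct_ip, ct_input10, dilution_factor = 3.32) {
  if (!all(is.finite(c(ct_ip, ct_input10, dilution_factor))))
    stop_ox("Ct values must be finite", class = "oxbspipe_validation_error")
  2^((ct_input10 - dilution_factor) - ct_ip) * 100
}

#' Compensatory factor for an input dilution
#'
#' @param d dilution denominator (10 for a 1:10 input).
#' @return log2(d), in cycles; 10 gives 3.3219..., printed as 3.32.
#' @export
dilution_factor <- function(d) {
  assert_scalar_number(d, "d", lower = .Machine$double.eps)
  log2(d)
}

#' SAM/SAH methylation index
#'
#' The cellular methylation potential: ratio of S-adenosylmethionine to
#' S-adenosylhomocysteine concentrations (same units).
#'
#' @param sam,sah non-negative concentrations; `sah` must be positive.
#' @return sam / sah (vectorized).
#' @export
methylation_index <- function(sam, sah) {
  if (any(sam < 0) || any(sah < 0))
    stop_ox("concentrations must be non-negative",
            class = "oxbspipe_validation_error")
  if (any(sah == 0))
    stop_ox("methylation index undefined at SAH = 0",
            class = "oxbspipe_validation_error")
  sam / sah
}
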