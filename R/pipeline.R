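#' Default pipeline configuration
#'
#' @param seed integer seed funnelled into every stage.
#' @param simulation list of [sim_config()] overrides (n_genes and
#'   chrom_length are forwarded to [generate_annotation()]).
#' @param thresholds list: detp, max_fail_frac, peak_delta, dhmp_delta,
#'   alpha, maxgap, min_cpgs.
#' @param contrasts list of length-2 vectors (target, reference).
#' @param normalize logical: run stratified quantile normalization.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, simulation = list(),
                            thresholds = list(), contrasts = NULL,
                            normalize = FALSE) {
  th <- utils::modifyList(list(detp = 0.01, max_fail_frac = 0.10,
                               peak_delta = 0.10, dhmp_delta = 0.20,
                               alpha = 0.05, maxgap = 1000, min_cpgs = 3),
                          thresholds)
  if (th$alpha < 0 || th$alpha > 1 || th$detp <= 0 || th$detp >= 1)
    stop_ox("thresholds outside documented ranges",
            class = "oxbspipe_validation_error")
  contrasts <- contrasts %||% list(c("differentiating", "proliferative"),
                                   c("ifc", "differentiating"))
  if (length(contrasts) < 1L)
    stop_ox("at least one contrast is required",
            class = "oxbspipe_validation_error")
  structure(list(seed = as.integer(seed), simulation = simulation,
                 thresholds = th, contrasts = contrasts,
                 normalize = isTRUE(normalize)),
            class = "pipeline_config")
}

#' Run the full paired BS/oxBS analysis
#'
#' Orchestrates simulate (or load) -> detection QC -> (optional
#' normalization) -> binomial MLE -> global 5hmC -> peak calling ->
#' position-level differential tests of 5hmC (on the MLE matrix) and 5mC
#' (on oxBS betas) -> proximity-based regions -> context annotation ->
#' metagene profiles -> gene-body summary, logging per-stage probe counts
#' and writing result tables plus a reproducibility manifest when
#' `out_dir` is given.
#'
#' @param config a [pipeline_config()], a plain list of its arguments, or
#'   the path to a YAML file holding them.
#' @param seed optional override of the config seed.
#' @param out_dir optional output directory for [write_results()].
#' @param quiet suppress progress messages.
#' @return Object of class `oxbs_pipeline_result`: the annotation, truth,
#'   arrays, QC report, estimates, global-loss table, peaks, per-contrast
#'   DhMP/DMP tables and regions, context annotation, metagene profiles,
#'   gene-body summary and manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), seed = NULL,
                         out_dir = NULL, quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!inherits(config, "pipeline_config"))
    config <- do.call(pipeline_config, config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  th <- config$thresholds
  say <- function(...) if (!quiet) message("[oxbspipe] ", ...)

  sim_args <- config$simulation
  ann_args <- sim_args[intersect(names(sim_args), c("n_genes", "chrom_length"))]
  sim_args <- sim_args[setdiff(names(sim_args), c("n_genes", "chrom_length"))]
  scfg <- do.call(sim_config, c(list(seed = config$seed), sim_args))
  say("simulating: seed ", config$seed)
  ann <- do.call(generate_annotation, c(list(seed = config$seed), ann_args))
  truth <- generate_truth(ann, scfg)
  arrays <- simulate_paired_arrays(truth, scfg)
  n_input <- nrow(arrays$bs$beta)
  say("input probes: ", n_input)

  qc <- filter_probes(arrays$bs, arrays$oxbs, detp_threshold = th$detp,
                      sample_frac = th$max_fail_frac)
  bs <- qc$bs; oxbs <- qc$oxbs
  say("post-QC probes: ", nrow(bs$beta), " (removed ", nrow(qc$report), ")")
  if (config$normalize) {
    bs <- normalize_stratified_quantile(bs)
    oxbs <- normalize_stratified_quantile(oxbs)
  }

  est <- estimate_methylome(bs, oxbs, arrays$samples, quiet = quiet)
  gloss <- global_hmc_loss(bs, oxbs, arrays$samples)
  delta <- naive_delta(bs, oxbs, arrays$samples)

  peaks <- do.call(rbind, lapply(unique(arrays$samples$condition), function(cc)
    call_hmc_peaks(delta, condition = cc, min_delta = th$peak_delta,
                   alpha = th$alpha)))

  cond_of_pair <- est$pairs$condition
  diffs <- list()
  for (ct in config$contrasts) {
    key <- paste(ct[1L], "vs", ct[2L])
    dhmp <- test_positions(est$h, cond_of_pair, ct,
                           delta_min = th$dhmp_delta, alpha = th$alpha)
    ox_design <- arrays$samples$condition[match(colnames(oxbs$beta),
                                                arrays$samples$sample_id)]
    dmp <- test_positions(oxbs$beta, ox_design, ct,
                          delta_min = th$dhmp_delta, alpha = th$alpha)
    pos <- cbind(bs$probes[match(dhmp$probe_id, bs$probes$probe_id),
                           c("chrom", "pos")], dhmp)
    regions <- call_regions(pos[order(pos$chrom, pos$pos), ],
                            maxgap = th$maxgap, min_cpgs = th$min_cpgs)
    say(key, ": ", sum(dhmp$significant, na.rm = TRUE), " DhMPs, ",
        sum(dmp$significant, na.rm = TRUE), " DMPs, ",
        nrow(regions), " regions")
    diffs[[key]] <- list(contrast = ct, dhmp = dhmp, dmp = dmp,
                         regions = regions)
  }

  ctx <- annotate_positions(bs$probes, ann)
  conds <- unique(arrays$samples$condition)
  metagene <- list()
  for (cc in conds) {
    cols <- est$pairs$pair_id[est$pairs$condition == cc]
    hbar <- rowMeans(est$h[, cols, drop = FALSE], na.rm = TRUE)
    mbar <- rowMeans(est$m[, cols, drop = FALSE], na.rm = TRUE)
    metagene[[paste0("h_", cc)]] <-
      metagene_profile(stats::setNames(hbar, rownames(est$h)), bs$probes, ann)
    metagene[[paste0("m_", cc)]] <-
      metagene_profile(stats::setNames(mbar, rownames(est$m)), bs$probes, ann)
  }
  body_summary <- gene_body_summary(est, ann)

  manifest <- list(package = "oxbspipe",
                   version = as.character(utils::packageVersion("oxbspipe")),
                   seed = config$seed, thresholds = th,
                   contrasts = lapply(config$contrasts, paste, collapse = ":"),
                   n_probes_input = n_input,
                   n_probes_post_qc = nrow(bs$beta),
                   timestamp = format(Sys.time(), tz = "UTC"))

  res <- structure(list(annotation = ann, truth = truth, arrays = arrays,
                        qc_report = qc$report, bs = bs, oxbs = oxbs,
                        estimate = est, global_loss = gloss, peaks = peaks,
                        differential = diffs, context = ctx,
                        metagene = metagene, body_summary = body_summary,
                        config = config, manifest = manifest),
                   class = "oxbs_pipeline_result")
  if (!is.null(out_dir)) {
    first <- diffs[[1L]]
    write_results(list(dhmp = first$dhmp, dmp = first$dmp,
                       peaks = peaks, regions = first$regions,
                       metagene = metagene, manifest = manifest), out_dir)
  }
  res
}

#' @export
print.oxbs_pipeline_result <- function(x, ...) {
  cat("oxbs_pipeline_result (seed ", x$config$seed, ")\n", sep = "")
  cat("  probes: ", x$manifest$n_probes_input, " input -> ",
      x$manifest$n_probes_post_qc, " post-QC\n", sep = "")
  s <- x$body_summary$summary
  cat("  gene-body means (%):\n")
  for (i in seq_len(nrow(s)))
    cat(sprintf("    %-16s 5mC %5.1f   5hmC %4.2f\n", s$condition[i],
                s$mean_m_pct[i], s$mean_h_pct[i]))
  for (nm in names(x$differential)) {
    d <- x$differential[[nm]]
    cat(sprintf("  %s: %d DhMPs, %d DMPs, %d regions\n", nm,
                sum(d$dhmp$significant, na.rm = TRUE),
                sum(d$dmp$significant, na.rm = TRUE), nrow(d$regions)))
  }
  invisible(x)
}
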