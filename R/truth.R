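#' Generate a ground-truth methylome on a toy genome
#'
#' Lays out array probes over the annotation (gene bodies, promoters, CpG
#' islands, sparse intergenic backbone) and draws per-probe true 5mC and
#' 5hmC fractions for every condition. Regional means encode the biology the
#' analysis is meant to recover: gene-body 5hmC calibrated to the
#' per-condition targets of the configuration, 5hmC gain concentrated on the
#' bodies of upregulated genes and on introns, and depressed 5hmC at
#' promoters and CpG islands. Per-probe truth is drawn from beta
#' distributions around the regional means (precision `precision_h` /
#' `precision_m`), using one shared quantile per probe across conditions so
#' that conditions are coherently ordered probe by probe. After drawing,
#' each condition's gene-body mean is rescaled to hit its configured target
#' exactly.
#'
#' @param annotation a `genome_annotation`.
#' @param config a [sim_config()].
#' @return An object of class `truth_methylome`: list with `probes`
#'   (probe_id, chrom, pos 1-based, construction labels) and `m`, `h`
#'   matrices (probes x conditions).
#' @export
generate_truth <- function(annotation, config) {
  validate_annotation(annotation)
  if (!inherits(config, "sim_config"))
    stop_ox("`config` must be a sim_config", class = "oxbspipe_validation_error")
  set.seed(config$seed + 1L)
  conds <- config$conditions
  genes <- annotation$genes
  chrom <- names(annotation$chrom_sizes)[1L]
  chrom_len <- annotation$chrom_sizes[[1L]]

  place <- function(lo, hi, n) {
    if (hi <= lo || n < 1L) return(integer(0))
    unique(as.integer(round(seq(lo, hi - 1L, length.out = n))))
  }

  probe_list <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    # body probes sit downstream of the promoter window, confined to the
    # 5'-most body_span_max bp (array probe density is 5'-biased, and this
    # keeps within-gene probe spacing well under region-calling gaps)
    body <- if (g$strand == "+")
      c(g$start + 501L, min(g$end, g$start + 501L + config$body_span_max)) else
      c(max(g$start, g$end - 501L - config$body_span_max), g$end - 501L)
    p_body <- place(body[1L], body[2L], config$probes_per_body)
    off <- c(-1200L, 200L)[seq_len(config$probes_per_promoter)]
    p_prom <- if (g$strand == "+") g$tss + off else g$tss - off
    p_prom <- p_prom[p_prom >= 0L & p_prom < chrom_len]
    probe_list[[length(probe_list) + 1L]] <- data.frame(
      p0 = c(p_body, p_prom),
      class_label = rep(c("body", "promoter"),
                        c(length(p_body), length(p_prom))),
      gene_id = g$gene_id, stringsAsFactors = FALSE)
  }
  if (nrow(annotation$cgis) && config$probes_per_cgi > 0L) {
    cg <- annotation$cgis
    probe_list[[length(probe_list) + 1L]] <- data.frame(
      p0 = as.integer((cg$start + cg$end) %/% 2L),
      class_label = "cgi", gene_id = NA_character_, stringsAsFactors = FALSE)
  }
  backbone <- seq(config$intergenic_spacing %/% 2L, chrom_len - 1L,
                  by = config$intergenic_spacing)
  near_gene <- vapply(backbone, function(p)
    any(p >= genes$start - 3000L & p < genes$end + 3000L), logical(1))
  probe_list[[length(probe_list) + 1L]] <- data.frame(
    p0 = as.integer(backbone[!near_gene]), class_label = "intergenic",
    gene_id = NA_character_, stringsAsFactors = FALSE)

  pr <- do.call(rbind, probe_list)
  pr <- pr[!duplicated(pr$p0), , drop = FALSE]
  pr <- pr[order(pr$p0), , drop = FALSE]
  pr$chrom <- chrom
  pr$p0 <- as.integer(pr$p0)
  pr$pos <- pr$p0 + 1L                     # 1-based CpG cytosine position
  pr$probe_id <- sprintf("cg%06d", seq_len(nrow(pr)))
  rownames(pr) <- pr$probe_id

  # exon/intron status of body probes
  ex <- annotation$exons
  in_exon <- !is.na(.interval_index_of(pr$p0, ex$start, ex$end))
  pr$subunit <- ifelse(pr$class_label != "body", NA_character_,
                       ifelse(in_exon, "exon", "intron"))

  # pipeline feature labels define the gene-body calibration set, so the
  # generator and the downstream summary agree on what "gene body" means
  feat <- annotate_positions(pr[c("probe_id", "chrom", "pos")], annotation)
  pr$feature <- feat$feature[match(pr$probe_id, feat$probe_id)]
  calib <- pr$feature %in% c("exon", "intron")
  if (!any(calib))
    stop_ox("no gene-body probes placed; increase probes_per_body",
            class = "oxbspipe_capacity_error")

  n <- nrow(pr)
  u_m <- stats::runif(n)
  u_h <- stats::runif(n)

  qdraw <- function(u, mean, prec) {
    out <- numeric(length(u))
    pos <- mean > 0 & mean < 1
    out[pos] <- stats::qbeta(u[pos], mean[pos] * prec, (1 - mean[pos]) * prec)
    out[mean >= 1] <- 1
    out
  }

  m <- h <- matrix(0, n, length(conds),
                   dimnames = list(pr$probe_id, conds))
  gset <- genes$gene_set[match(pr$gene_id, genes$gene_id)]
  iew <- ifelse(is.na(pr$subunit), 1,
                ifelse(pr$subunit == "exon", config$exon_weight,
                       config$intron_weight))

  # planted strong-gain blocks: consecutive central body probes of the
  # first n up-regulated genes (ground truth for DhMP/region calling)
  blocks <- NULL
  pr$block_id <- NA_integer_
  if (config$n_planted_blocks > 0L && config$block_size > 0L &&
      any(config$h_body > 0)) {
    up_genes <- sort(genes$gene_id[genes$gene_set == "up"])
    bid <- 0L
    for (gid in up_genes) {
      if (bid >= config$n_planted_blocks) break
      idx <- which(pr$gene_id %in% gid & pr$class_label == "body" &
                     pr$feature %in% c("exon", "intron"))
      if (length(idx) < config$block_size) next
      bid <- bid + 1L
      mid <- (length(idx) - config$block_size) %/% 2L
      take <- idx[mid + seq_len(config$block_size)]
      pr$block_id[take] <- bid
      blocks <- rbind(blocks, data.frame(
        block_id = bid, gene_id = gid, chrom = chrom,
        start = min(pr$p0[take]), end = max(pr$p0[take]) + 1L,
        probe_ids = paste(pr$probe_id[take], collapse = ","),
        stringsAsFactors = FALSE))
    }
  }
  in_block <- !is.na(pr$block_id)

  baseline <- conds[1L]
  for (cc in conds) {
    gsw <- config$gs_weights_h[[cc]][gset]
    gsw[is.na(gsw)] <- 1
    mu_h <- switch_means(pr$class_label, config, cc, gsw * iew)$h
    mu_m <- switch_means(pr$class_label, config, cc, gsw * iew)$m
    h[, cc] <- qdraw(u_h, mu_h, config$precision_h)
    m[, cc] <- qdraw(u_m, mu_m, config$precision_m)
    if (config$m_body[[cc]] > 0 && mean(m[calib, cc]) > 0)
      m[, cc] <- m[, cc] * (config$m_body[[cc]] / mean(m[calib, cc]))
  }
  # block probes get an elevated baseline in every condition (above the
  # noise floor of the paired measurement), then the planted gain on top
  if (any(in_block))
    for (cc in conds)
      if (config$h_body[[cc]] > 0)
        h[in_block, cc] <- config$block_baseline_h
  # calibrate gene-body 5hmC means to targets; conditions carrying planted
  # blocks fix the block probes at baseline + block_delta and absorb the
  # calibration in the remaining probes
  for (cc in conds) {
    target <- config$h_body[[cc]]
    planted <- cc %in% config$block_conditions && any(in_block) && target > 0
    if (!planted) {
      if (target > 0 && mean(h[calib, cc]) > 0)
        h[, cc] <- h[, cc] * (target / mean(h[calib, cc]))
    }
  }
  for (cc in setdiff(conds, baseline)) {
    target <- config$h_body[[cc]]
    planted <- cc %in% config$block_conditions && any(in_block) && target > 0
    if (planted) {
      h[in_block, cc] <- h[in_block, baseline] + config$block_delta
      rest <- calib & !in_block
      need <- target * sum(calib) - sum(h[in_block & calib, cc])
      s <- need / sum(h[rest, cc])
      if (!is.finite(s) || s <= 0)
        stop_ox("infeasible gene-body 5hmC target %g with planted blocks",
                target, class = "oxbspipe_validation_error")
      h[!in_block, cc] <- h[!in_block, cc] * s
    }
  }
  for (cc in conds) h[, cc] <- pmin(h[, cc], 1 - m[, cc])

  structure(list(probes = pr[c("probe_id", "chrom", "pos", "class_label",
                               "gene_id", "subunit", "feature", "block_id")],
                 m = m, h = h, conditions = conds, blocks = blocks),
            class = "truth_methylome")
}

# regional means per probe class for one condition; `wh` is the per-probe
# gene-body 5hmC weight (gene-set x intron/exon), applied to body probes only
#' @noRd
switch_means <- function(class_label, config, cond, wh) {
  hb <- config$h_body[[cond]]
  mb <- config$m_body[[cond]]
  mu_h <- ifelse(class_label == "body", hb * wh,
          ifelse(class_label == "promoter", config$promoter_h_frac * hb,
          ifelse(class_label == "cgi", config$cgi_h_frac * hb,
                 config$intergenic_h_frac * hb)))
  mu_m <- ifelse(class_label == "body", mb,
          ifelse(class_label == "promoter", 0.10,
          ifelse(class_label == "cgi", 0.08, 0.70)))
  list(h = pmin(mu_h, 0.99), m = mu_m)
}

#' @export
print.truth_methylome <- function(x, ...) {
  cat("truth_methylome:", nrow(x$probes), "probes x",
      length(x$conditions), "conditions\n")
  body <- x$probes$feature %in% c("exon", "intron")
  cat("  gene-body mean true 5hmC (%):",
      paste(sprintf("%s=%.2f", x$conditions,
                    100 * colMeans(x$h[body, , drop = FALSE])),
            collapse = ", "), "\n")
  invisible(x)
}
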