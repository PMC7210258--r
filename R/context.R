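#' Annotate CpG positions to genomic context
#'
#' Assigns each probe exactly one gene-feature label with precedence
#' promoter > exon > intron > intergenic (the promoter window is
#' `promoter_window` bp around the TSS in gene orientation), a CpG-island
#' context (island; shore within 2 kb of an island edge; shelf within
#' 2-4 kb; open sea beyond), the chromatin state of the segment containing
#' the probe, and the nearest gene by TSS distance (signed, negative
#' upstream of the TSS in gene orientation; ties broken toward the
#' lexicographically smaller gene_id).
#'
#' @param probes data.frame with probe_id, chrom, pos (1-based).
#' @param annotation a `genome_annotation`.
#' @param promoter_window numeric length 2, offsets around the TSS in gene
#'   orientation (default c(-2000, 500)).
#' @return data.frame: probe_id, feature, cgi_context, chrom_state,
#'   nearest_gene_id, tss_distance.
#' @export
annotate_positions <- function(probes, annotation,
                               promoter_window = c(-2000, 500)) {
  unknown <- setdiff(unique(probes$chrom), names(annotation$chrom_sizes))
  if (length(unknown))
    stop_ox("probes on unknown chromosome(s): %s",
            paste(unknown, collapse = ", "),
            class = "oxbspipe_annotation_error")
  p0 <- probes$pos - 1L
  g <- annotation$genes

  # oriented promoter interval per gene, clamped to the chromosome
  plus <- g$strand == "+"
  pstart <- ifelse(plus, g$tss + promoter_window[1L],
                   g$tss - promoter_window[2L])
  pend <- ifelse(plus, g$tss + promoter_window[2L] + 1L,
                 g$tss - promoter_window[1L] + 1L)
  pstart <- pmax(pstart, 0)
  pend <- pmin(pend, annotation$chrom_sizes[g$chrom])

  in_prom <- !is.na(.interval_index_of(p0, pstart, pend))
  in_exon <- !is.na(.interval_index_of(p0, annotation$exons$start,
                                       annotation$exons$end))
  in_gene <- !is.na(.interval_index_of(p0, g$start, g$end))
  feature <- ifelse(in_prom, "promoter",
             ifelse(in_exon, "exon",
             ifelse(in_gene, "intron", "intergenic")))

  cg <- annotation$cgis
  d_cgi <- .dist_to_intervals(p0, cg$start, cg$end)
  cgi_context <- ifelse(d_cgi == 0, "island",
                 ifelse(d_cgi <= 2000, "shore",
                 ifelse(d_cgi <= 4000, "shelf", "open_sea")))

  st_idx <- .interval_index_of(p0, annotation$states$start,
                               annotation$states$end)
  chrom_state <- annotation$states$state[st_idx]

  # nearest gene by |TSS distance|; deterministic tie-break on gene_id
  og <- g[order(g$gene_id), ]
  dmat <- abs(outer(p0, og$tss, "-"))
  near <- max.col(-dmat, ties.method = "first")
  nearest_gene_id <- og$gene_id[near]
  tss_distance <- ifelse(og$strand[near] == "+",
                         p0 - og$tss[near], og$tss[near] - p0)

  data.frame(probe_id = probes$probe_id, feature = feature,
             cgi_context = cgi_context, chrom_state = chrom_state,
             nearest_gene_id = nearest_gene_id, tss_distance = tss_distance,
             stringsAsFactors = FALSE)
}

#' Category enrichment of a probe set against the array background
#'
#' For each category, builds the 2x2 table of category membership for the
#' foreground versus the background minus the foreground, with a two-sided
#' Fisher exact p-value and the sample odds ratio (Haldane +0.5 correction
#' only when a zero cell occurs), BH-adjusted across categories. When the
#' foreground exhausts the background there is no complement to compare
#' against: the odds ratio is reported as 1 and p as 1.
#'
#' @param foreground,background probe id vectors, foreground a subset of
#'   background.
#' @param labels named character vector mapping every background probe to
#'   its category.
#' @return data.frame: category, fg_count, fg_frac, bg_frac, odds_ratio,
#'   p, fdr.
#' @export
enrichment_vs_background <- function(foreground, background, labels) {
  if (length(foreground) == 0L)
    stop_ox("empty foreground", class = "oxbspipe_validation_error")
  if (!all(foreground %in% background))
    stop_ox("foreground must be a subset of the background",
            class = "oxbspipe_validation_error")
  if (!all(background %in% names(labels)))
    stop_ox("`labels` must cover every background probe",
            class = "oxbspipe_validation_error")
  rest <- setdiff(background, foreground)
  cats <- sort(unique(labels[background]))
  out <- do.call(rbind, lapply(cats, function(cat) {
    a <- sum(labels[foreground] == cat); b <- length(foreground) - a
    c <- sum(labels[rest] == cat); d <- length(rest) - c
    if (c + d == 0L) {
      or <- 1; p <- 1
    } else {
      p <- stats::fisher.test(matrix(c(a, b, c, d), 2L))$p.value
      tab <- c(a, b, c, d)
      if (any(tab == 0L)) tab <- tab + 0.5
      or <- (tab[1L] * tab[4L]) / (tab[2L] * tab[3L])
    }
    data.frame(category = cat, fg_count = a,
               fg_frac = a / length(foreground),
               bg_frac = sum(labels[background] == cat) / length(background),
               odds_ratio = or, p = p, stringsAsFactors = FALSE)
  }))
  out$fdr <- adjust_bh(out$p)
  rownames(out) <- NULL
  out
}

#' Strand-aware metagene profile
#'
#' Averages a per-probe signal over genes after scaling each gene body to
#' `body_bins` equal fractions TSS to TES in gene orientation (minus-strand
#' genes flipped) with `flank_bins` fixed-width bins on either flank.
#' Profiles are computed per gene-set label; bin means skip missing signal.
#'
#' @param signal named numeric vector, probe_id -> value (NA allowed).
#' @param probes data.frame with probe_id, chrom, pos (1-based).
#' @param annotation a `genome_annotation`.
#' @param gene_sets gene-set labels to profile (default up, down,
#'   housekeeping).
#' @param flank flank width in bp.
#' @param body_bins,flank_bins bin counts.
#' @return Object of class `metagene_profile`: `mean` and `count` matrices
#'   (gene sets x bins), plus the bin scheme.
#' @export
metagene_profile <- function(signal, probes, annotation,
                             gene_sets = c("up", "down", "housekeeping"),
                             flank = 2000, body_bins = 20, flank_bins = 5) {
  nbins <- 2L * flank_bins + body_bins
  binw <- flank / flank_bins
  sets <- intersect(gene_sets, unique(annotation$genes$gene_set))
  sums <- counts <- matrix(0, length(sets), nbins,
                           dimnames = list(sets, sprintf("bin%02d", 1:nbins)))
  p0 <- probes$pos - 1L
  sig <- signal[probes$probe_id]
  for (i in seq_len(nrow(annotation$genes))) {
    gn <- annotation$genes[i, ]
    if (!(gn$gene_set %in% sets)) next
    len <- gn$end - gn$start
    if (len <= 0L) { warning("zero-length gene skipped: ", gn$gene_id); next }
    inw <- which(probes$chrom == gn$chrom & p0 >= gn$start - flank &
                   p0 < gn$end + flank)
    if (!length(inw)) next
    rel <- if (gn$strand == "+") p0[inw] - gn$start else (gn$end - 1L) - p0[inw]
    bin <- integer(length(rel))
    up <- rel < 0
    bin[up] <- flank_bins + 1L + floor(rel[up] / binw)      # 1..flank_bins
    body <- rel >= 0 & rel < len
    bin[body] <- flank_bins + 1L + floor(rel[body] / len * body_bins)
    down <- rel >= len
    bin[down] <- flank_bins + body_bins +
      pmin(flank_bins, 1L + floor((rel[down] - len) / binw))
    keep <- bin >= 1L & bin <= nbins & !is.na(sig[inw])
    for (k in which(keep)) {
      sums[gn$gene_set, bin[k]] <- sums[gn$gene_set, bin[k]] + sig[inw][k]
      counts[gn$gene_set, bin[k]] <- counts[gn$gene_set, bin[k]] + 1
    }
  }
  means <- sums / counts
  means[counts == 0] <- NA_real_
  structure(list(mean = means, count = counts,
                 scheme = list(flank = flank, body_bins = body_bins,
                               flank_bins = flank_bins)),
            class = "metagene_profile")
}

#' @export
print.metagene_profile <- function(x, ...) {
  cat("metagene_profile:", nrow(x$mean), "gene set(s) x", ncol(x$mean),
      "bins (", x$scheme$flank_bins, "flank +", x$scheme$body_bins,
      "body +", x$scheme$flank_bins, "flank )\n")
  print(round(x$mean[, seq(1L, ncol(x$mean), length.out = 6L), drop = FALSE], 4))
  invisible(x)
}

#' Gene-body 5mC/5hmC summary with between-condition tests
#'
#' Reports, per condition, the mean 5mC and 5hmC estimate over all defined
#' (non-NA) cells at gene-body probes (feature exon or intron), in percent,
#' and compares conditions pairwise with the rank-sum test on per-gene
#' body means.
#'
#' @param est a `methylome_estimate`.
#' @param annotation a `genome_annotation`.
#' @param gene_sets optional subset of gene-set labels whose genes define
#'   the bodies (default: all genes).
#' @return list: `summary` (condition, mean_m_pct, mean_h_pct, n_cells,
#'   h_na_frac), `tests` (condition_a, condition_b, mark, p), `per_gene`
#'   (gene x condition matrices of body means).
#' @export
gene_body_summary <- function(est, annotation, gene_sets = NULL) {
  ctx <- annotate_positions(est$probes, annotation)
  body <- ctx$feature %in% c("exon", "intron")
  if (!is.null(gene_sets)) {
    keep_genes <- annotation$genes$gene_id[annotation$genes$gene_set %in% gene_sets]
    body <- body & ctx$nearest_gene_id %in% keep_genes
  }
  if (!any(body))
    stop_ox("no gene-body probes", class = "oxbspipe_validation_error")
  conds <- unique(est$pairs$condition)
  gene_of <- ctx$nearest_gene_id[body]
  hs <- est$h[body, , drop = FALSE]
  ms <- est$m[body, , drop = FALSE]
  summ <- do.call(rbind, lapply(conds, function(cc) {
    cols <- est$pairs$pair_id[est$pairs$condition == cc]
    hcells <- hs[, cols, drop = FALSE]
    mcells <- ms[, cols, drop = FALSE]
    if (all(is.na(hcells)))
      warning("condition ", cc, ": no defined 5hmC cells on gene bodies")
    data.frame(condition = cc,
               mean_m_pct = 100 * mean(mcells, na.rm = TRUE),
               mean_h_pct = 100 * mean(hcells, na.rm = TRUE),
               n_cells = sum(!is.na(hcells)),
               h_na_frac = mean(is.na(hcells)),
               stringsAsFactors = FALSE)
  }))
  per_gene_h <- sapply(conds, function(cc) {
    cols <- est$pairs$pair_id[est$pairs$condition == cc]
    tapply(rowMeans(hs[, cols, drop = FALSE], na.rm = TRUE), gene_of,
           mean, na.rm = TRUE)
  })
  per_gene_m <- sapply(conds, function(cc) {
    cols <- est$pairs$pair_id[est$pairs$condition == cc]
    tapply(rowMeans(ms[, cols, drop = FALSE], na.rm = TRUE), gene_of,
           mean, na.rm = TRUE)
  })
  cmb <- utils::combn(conds, 2L)
  tests <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(k) {
    a <- cmb[1L, k]; b <- cmb[2L, k]
    rbind(
      data.frame(condition_a = a, condition_b = b, mark = "5hmC",
                 p = compare_groups_wilcoxon(
                   per_gene_h[, a][is.finite(per_gene_h[, a])],
                   per_gene_h[, b][is.finite(per_gene_h[, b])])$p),
      data.frame(condition_a = a, condition_b = b, mark = "5mC",
                 p = compare_groups_wilcoxon(
                   per_gene_m[, a][is.finite(per_gene_m[, a])],
                   per_gene_m[, b][is.finite(per_gene_m[, b])])$p))
  }))
  list(summary = summ, tests = tests,
       per_gene = list(h = per_gene_h, m = per_gene_m))
}

#' Hypergeometric gene-set overlap test
#'
#' Overlap of two gene sets within a universe: observed count, expectation
#' under independence, fold enrichment, and the exact upper-tail
#' hypergeometric probability P[X >= k].
#'
#' @param set_a,set_b gene id vectors, subsets of `universe`.
#' @param universe gene id vector (non-empty).
#' @return list: k, expected, fold, p.
#' @export
overlap_hypergeometric <- function(set_a, set_b, universe) {
  if (length(universe) == 0L)
    stop_ox("empty universe", class = "oxbspipe_validation_error")
  set_a <- unique(set_a); set_b <- unique(set_b); universe <- unique(universe)
  if (!all(set_a %in% universe) || !all(set_b %in% universe))
    stop_ox("sets must be subsets of the universe",
            class = "oxbspipe_validation_error")
  k <- length(intersect(set_a, set_b))
  expected <- length(set_a) * length(set_b) / length(universe)
  p <- stats::phyper(k - 1L, length(set_a), length(universe) - length(set_a),
                     length(set_b), lower.tail = FALSE)
  list(k = k, expected = expected,
       fold = if (expected > 0) k / expected else NA_real_, p = p)
}
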