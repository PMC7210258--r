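#' Construct a genome annotation object
#'
#' Internal coordinates are 0-based half-open throughout (`start` inclusive,
#' `end` exclusive), matching BED arithmetic; `tss` is the 0-based position
#' of the first transcribed base (= `start` on the plus strand, `end - 1` on
#' the minus strand).
#'
#' @param chrom_sizes named numeric vector, chromosome lengths in bp.
#' @param genes data.frame with columns gene_id, chrom, start, end, strand,
#'   tss, gene_set (one of up/down/housekeeping/none).
#' @param exons data.frame with columns gene_id, chrom, start, end.
#' @param cgis data.frame with columns chrom, start, end (CpG islands).
#' @param states data.frame with columns chrom, start, end, state
#'   (chromatin-state tiling).
#' @return A validated object of class `genome_annotation`.
#' @export
genome_annotation <- function(chrom_sizes, genes, exons, cgis, states) {
  ann <- structure(list(chrom_sizes = chrom_sizes, genes = genes,
                        exons = exons, cgis = cgis, states = states),
                   class = "genome_annotation")
  validate_annotation(ann)
  ann
}

#' @noRd
validate_annotation <- function(ann) {
  gs <- ann$genes
  if (nrow(gs) < 1L)
    stop_ox("annotation must contain at least one gene",
            class = "oxbspipe_validation_error")
  for (tab in list(ann$genes, ann$exons, ann$cgis, ann$states)) {
    if (nrow(tab) == 0L) next
    if (any(tab$end <= tab$start))
      stop_ox("interval with end <= start in annotation",
              class = "oxbspipe_format_error")
    sz <- ann$chrom_sizes[tab$chrom]
    if (any(is.na(sz)) || any(tab$start < 0) || any(tab$end > sz))
      stop_ox("interval outside chromosome bounds",
              class = "oxbspipe_format_error")
  }
  if (anyDuplicated(gs$gene_id))
    stop_ox("duplicate gene_id in annotation", class = "oxbspipe_format_error")
  if (!all(gs$gene_set %in% c("up", "down", "housekeeping", "none")))
    stop_ox("gene_set labels must be up/down/housekeeping/none",
            class = "oxbspipe_format_error")
  # exons nested in their gene span and non-overlapping within a gene
  ex <- ann$exons
  if (nrow(ex)) {
    sp <- gs[match(ex$gene_id, gs$gene_id), ]
    if (any(is.na(sp$start)) || any(ex$start < sp$start) || any(ex$end > sp$end))
      stop_ox("exon outside its gene span", class = "oxbspipe_format_error")
    by_gene <- split(ex[c("start", "end")], ex$gene_id)
    for (e in by_gene) {
      e <- e[order(e$start), ]
      if (nrow(e) > 1L && any(e$start[-1L] < e$end[-nrow(e)]))
        stop_ox("overlapping exons within a gene", class = "oxbspipe_format_error")
    }
  }
  invisible(ann)
}

#' Generate a toy annotated genome
#'
#' Places non-overlapping genes with exon/intron structure on a single toy
#' chromosome, assigns each gene an expression-based gene-set label
#' (up/down/housekeeping/none) in configurable proportions, drops a CpG
#' island over a configurable fraction of transcription start sites, and
#' tiles the chromosome with chromatin-state segments. Deterministic for a
#' fixed seed.
#'
#' @param seed integer seed.
#' @param n_genes number of genes (>= 1).
#' @param chrom_length chromosome length in bp; must leave room for
#'   `n_genes` non-overlapping gene footprints.
#' @param chrom chromosome name.
#' @param gene_set_props named proportions for up/down/housekeeping labels
#'   (remainder is "none").
#' @param cgi_tss_frac fraction of TSSs covered by a CpG island.
#' @return A `genome_annotation`.
#' @export
generate_annotation <- function(seed, n_genes = 50L, chrom_length = 5e6,
                                chrom = "chr1",
                                gene_set_props = c(up = 0.25, down = 0.25,
                                                   housekeeping = 0.10),
                                cgi_tss_frac = 0.6) {
  assert_scalar_number(seed, "seed")
  if (!is.numeric(n_genes) || length(n_genes) != 1L || n_genes < 1L)
    stop_ox("`n_genes` must be >= 1", class = "oxbspipe_validation_error")
  n_genes <- as.integer(n_genes)
  max_len <- 20000L; margin <- 3000L
  slot <- floor(chrom_length / n_genes)
  if (slot < max_len + 2L * margin)
    stop_ox(paste("cannot place %d non-overlapping genes on %g bp:",
                  "need at least %d bp per gene"),
            n_genes, chrom_length, max_len + 2L * margin,
            class = "oxbspipe_capacity_error")
  set.seed(as.integer(seed))

  len <- sample(8000:20000, n_genes, replace = TRUE)
  offset <- vapply(slot - len - 2L * margin,
                   function(k) sample.int(k, 1L), integer(1))
  start <- as.integer((seq_len(n_genes) - 1L) * slot + margin + offset)
  end <- as.integer(start + len)
  strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  tss <- as.integer(ifelse(strand == "+", start, end - 1L))
  gene_id <- sprintf("g%03d", seq_len(n_genes))

  # gene-set labels with fixed proportions (counts rounded once, then permuted)
  n_up <- round(gene_set_props[["up"]] * n_genes)
  n_dn <- round(gene_set_props[["down"]] * n_genes)
  n_hk <- round(gene_set_props[["housekeeping"]] * n_genes)
  labels <- c(rep("up", n_up), rep("down", n_dn), rep("housekeeping", n_hk),
              rep("none", n_genes - n_up - n_dn - n_hk))
  gene_set <- sample(labels)

  genes <- data.frame(gene_id = gene_id, chrom = chrom, start = start,
                      end = end, strand = strand, tss = tss,
                      gene_set = gene_set, stringsAsFactors = FALSE)

  exons <- do.call(rbind, lapply(seq_len(n_genes), function(i) {
    k <- sample(3:7, 1L)
    # 2k+1 alternating segments (exon/intron/.../exon) spanning the gene
    w <- stats::runif(2L * k - 1L)
    w <- round(w / sum(w) * len[i])
    b <- start[i] + c(0L, cumsum(w))
    b <- cummax(pmin(b, end[i]))
    b[length(b)] <- end[i]
    es <- as.integer(b[seq(1L, 2L * k - 1L, by = 2L)])
    ee <- as.integer(b[seq(2L, 2L * k, by = 2L)])
    keep <- ee > es
    data.frame(gene_id = gene_id[i], chrom = chrom,
               start = es[keep], end = ee[keep], stringsAsFactors = FALSE)
  }))

  with_cgi <- sample(n_genes, round(cgi_tss_frac * n_genes))
  cw <- sample(600:1500, length(with_cgi), replace = TRUE)
  cs <- pmax(0L, as.integer(tss[with_cgi] - cw %/% 2L))
  cgis <- data.frame(chrom = chrom, start = cs,
                     end = pmin(as.integer(chrom_length), cs + cw),
                     stringsAsFactors = FALSE)
  cgis <- cgis[order(cgis$start), , drop = FALSE]
  rownames(cgis) <- NULL

  # chromatin-state tiling over the whole chromosome
  state_pool <- c("Promoter", "Weak Txn", "Txn Elongation", "Enhancer",
                  "Quiescent")
  seg <- integer(0); pos <- 0
  while (pos < chrom_length) {
    seg <- c(seg, min(sample(5000:50000, 1L), chrom_length - pos))
    pos <- pos + seg[length(seg)]
  }
  ss <- as.integer(cumsum(c(0L, seg[-length(seg)])))
  states <- data.frame(chrom = chrom, start = ss, end = as.integer(ss + seg),
                       state = sample(state_pool, length(seg), replace = TRUE,
                                      prob = c(0.1, 0.3, 0.25, 0.1, 0.25)),
                       stringsAsFactors = FALSE)

  genome_annotation(chrom_sizes = stats::setNames(chrom_length, chrom),
                    genes = genes, exons = exons, cgis = cgis, states = states)
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("genome_annotation:", length(x$chrom_sizes), "chromosome(s),",
      nrow(x$genes), "genes,", nrow(x$exons), "exons,",
      nrow(x$cgis), "CGIs,", nrow(x$states), "chromatin-state segments\n")
  cat("  gene sets:", paste(sprintf("%s=%d", names(table(x$genes$gene_set)),
                                    table(x$genes$gene_set)), collapse = ", "),
      "\n")
  invisible(x)
}
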