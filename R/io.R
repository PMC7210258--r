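#' Write a beta matrix to TSV
#'
#' Layout: probe_id, chrom, pos (1-based CpG cytosine), then one column per
#' sample. Detection p-values and coverage go to companion TSVs of the same
#' layout when paths are supplied.
#'
#' @param bm a `beta_matrix`.
#' @param path beta TSV path.
#' @param detection_path,coverage_path optional companion TSV paths.
#' @return Invisibly, the paths written.
#' @export
write_beta_matrix <- function(bm, path, detection_path = NULL,
                              coverage_path = NULL) {
  dump <- function(mat, p) {
    df <- cbind(bm$probes[c("probe_id", "chrom", "pos")],
                as.data.frame(mat, check.names = FALSE))
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  dump(bm$beta, path)
  if (!is.null(detection_path)) dump(bm$detection_p, detection_path)
  if (!is.null(coverage_path)) dump(bm$coverage, coverage_path)
  invisible(c(path, detection_path, coverage_path))
}

#' Load a beta matrix from TSV
#'
#' Reads a beta TSV (probe_id, chrom, pos, one column per sample) and its
#' detection-p companion, validating every cell; out-of-range values are
#' rejected with the offending probe and sample named. Coverage may come
#' from a companion TSV or a scalar default applied to every cell.
#'
#' @param path beta TSV.
#' @param detection_path detection-p TSV with the same probe set and samples.
#' @param coverage path to a coverage TSV, or a scalar pseudo-coverage.
#' @param channel "BS" or "oxBS".
#' @return A validated `beta_matrix`.
#' @export
load_beta_matrix <- function(path, detection_path, coverage = 1000,
                             channel = c("BS", "oxBS")) {
  channel <- match.arg(channel)
  slurp <- function(p) {
    df <- utils::read.delim(p, check.names = FALSE, stringsAsFactors = FALSE)
    need <- c("probe_id", "chrom", "pos")
    if (!all(need %in% names(df)))
      stop_ox("%s: expected columns probe_id, chrom, pos", p,
              class = "oxbspipe_format_error")
    mat <- as.matrix(df[setdiff(names(df), need)])
    rownames(mat) <- df$probe_id
    list(probes = df[need], mat = mat)
  }
  b <- slurp(path)
  d <- slurp(detection_path)
  if (!identical(b$probes$probe_id, d$probes$probe_id) ||
      !identical(colnames(b$mat), colnames(d$mat)))
    stop_ox("probe/sample set mismatch between %s and %s", path,
            detection_path, class = "oxbspipe_alignment_error")
  cov <- if (is.character(coverage)) {
    cv <- slurp(coverage)
    if (!identical(cv$probes$probe_id, b$probes$probe_id))
      stop_ox("probe set mismatch between %s and %s", path, coverage,
              class = "oxbspipe_alignment_error")
    cv$mat
  } else {
    assert_scalar_number(coverage, "coverage", lower = 1)
    coverage
  }
  beta_matrix(b$mat, d$mat, cov, b$probes, channel)
}

#' Write/read the sample sheet as CSV
#' @param sheet sample sheet data.frame.
#' @param path CSV path.
#' @return `write_sample_sheet` the path invisibly; `load_sample_sheet`
#'   the sheet.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.csv(sheet, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_sample_sheet
#' @export
load_sample_sheet <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

# ---- annotation io ---------------------------------------------------------
# GFF3 is 1-based inclusive on disk, BED 0-based half-open; the in-memory
# annotation is 0-based half-open, so GFF shifts start by 1 on the way in/out
# and BED round-trips unchanged.

#' Write a genome annotation to standard formats
#'
#' Gene models go to GFF3 (gene + exon features) and BED12 (one line per
#' gene with exon blocks), CpG islands and chromatin states to BED, and
#' gene-set labels to CSV.
#'
#' @param ann a `genome_annotation`.
#' @param dir output directory (created if needed).
#' @return Invisibly, a named vector of the files written.
#' @export
write_annotation <- function(ann, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(gff = file.path(dir, "genes.gff3"),
             bed12 = file.path(dir, "genes.bed"),
             cgi = file.path(dir, "cgi.bed"),
             states = file.path(dir, "chrom_states.bed"),
             gene_sets = file.path(dir, "gene_sets.csv"))
  g <- ann$genes
  gr_genes <- GenomicRanges::GRanges(
    g$chrom, IRanges::IRanges(g$start + 1L, g$end), strand = g$strand,
    type = "gene", ID = g$gene_id)
  e <- ann$exons
  gr_exons <- GenomicRanges::GRanges(
    e$chrom, IRanges::IRanges(e$start + 1L, e$end),
    strand = g$strand[match(e$gene_id, g$gene_id)],
    type = "exon", ID = sprintf("%s.e%d", e$gene_id, seq_len(nrow(e))),
    Parent = e$gene_id)
  rtracklayer::export.gff3(c(gr_genes, gr_exons), paths[["gff"]])

  exl <- GenomicRanges::GRangesList(lapply(split(e, e$gene_id), function(ee)
    GenomicRanges::GRanges(ee$chrom, IRanges::IRanges(ee$start + 1L, ee$end))))
  bed12 <- rtracklayer::asBED(exl[g$gene_id])
  S4Vectors::mcols(bed12)$name <- g$gene_id
  GenomicRanges::strand(bed12) <- g$strand
  rtracklayer::export.bed(bed12, paths[["bed12"]])

  to_bed <- function(df, names, path) {
    gr <- GenomicRanges::GRanges(df$chrom,
                                 IRanges::IRanges(df$start + 1L, df$end),
                                 name = names)
    rtracklayer::export.bed(gr, path)
  }
  to_bed(ann$cgis, sprintf("cgi_%d", seq_len(nrow(ann$cgis))), paths[["cgi"]])
  to_bed(ann$states, ann$states$state, paths[["states"]])
  utils::write.csv(g[c("gene_id", "gene_set")], paths[["gene_sets"]],
                   row.names = FALSE, quote = FALSE)
  # chromosome sizes travel alongside so load_annotation can validate bounds
  utils::write.table(data.frame(chrom = names(ann$chrom_sizes),
                                size = as.numeric(ann$chrom_sizes)),
                     file.path(dir, "chrom_sizes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Load a genome annotation from GFF3/BED/CSV
#'
#' @param gff_path gene models, GFF3 (1-based inclusive; `gene` rows define
#'   spans, `exon` rows with a Parent attribute define exon structure).
#' @param cgi_bed,states_bed BED files (0-based half-open); the BED name
#'   field of `states_bed` carries the chromatin-state label.
#' @param gene_sets_csv CSV with gene_id, gene_set columns; genes absent
#'   from it (or unknown gene_ids in it, which trigger a warning) default
#'   to "none".
#' @param chrom_sizes named vector, or path to a two-column TSV.
#' @return A validated `genome_annotation` in 0-based half-open coordinates.
#' @export
load_annotation <- function(gff_path, cgi_bed, states_bed, gene_sets_csv,
                            chrom_sizes) {
  if (is.character(chrom_sizes) && length(chrom_sizes) == 1L &&
      file.exists(chrom_sizes)) {
    cs <- utils::read.delim(chrom_sizes, stringsAsFactors = FALSE)
    chrom_sizes <- stats::setNames(cs$size, cs$chrom)
  }
  gff <- rtracklayer::import.gff3(gff_path)
  gtype <- as.character(gff$type)
  gg <- gff[gtype == "gene"]
  ee <- gff[gtype == "exon"]
  genes <- data.frame(
    gene_id = as.character(gg$ID),
    chrom = as.character(GenomicRanges::seqnames(gg)),
    start = GenomicRanges::start(gg) - 1L, end = GenomicRanges::end(gg),
    strand = as.character(GenomicRanges::strand(gg)),
    stringsAsFactors = FALSE)
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  parent <- vapply(ee$Parent, function(p) as.character(p)[1L], character(1))
  exons <- data.frame(
    gene_id = parent,
    chrom = as.character(GenomicRanges::seqnames(ee)),
    start = GenomicRanges::start(ee) - 1L, end = GenomicRanges::end(ee),
    stringsAsFactors = FALSE)

  from_bed <- function(path) {
    gr <- rtracklayer::import.bed(path)
    data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
               start = GenomicRanges::start(gr) - 1L,
               end = GenomicRanges::end(gr),
               name = if (!is.null(gr$name)) as.character(gr$name) else NA,
               stringsAsFactors = FALSE)
  }
  cgis <- from_bed(cgi_bed)[c("chrom", "start", "end")]
  st <- from_bed(states_bed)
  states <- data.frame(chrom = st$chrom, start = st$start, end = st$end,
                       state = st$name, stringsAsFactors = FALSE)

  gsets <- utils::read.csv(gene_sets_csv, stringsAsFactors = FALSE)
  unknown <- setdiff(gsets$gene_id, genes$gene_id)
  if (length(unknown))
    warning(sprintf("gene_sets: %d unknown gene_id(s) ignored (e.g. %s)",
                    length(unknown), unknown[1L]))
  genes$gene_set <- gsets$gene_set[match(genes$gene_id, gsets$gene_id)]
  genes$gene_set[is.na(genes$gene_set)] <- "none"

  genome_annotation(chrom_sizes, genes, exons, cgis, states)
}

# ---- result io -------------------------------------------------------------

#' Write pipeline result tables
#'
#' Position-level tables go to TSV (header-only files when empty), regions
#' to BED6 (score = -log10 of the combined FDR times 100, capped at 1000)
#' plus a full TSV, metagene matrices to TSV, and a reproducibility
#' manifest (config, seed, package version, timestamp) to JSON.
#'
#' @param results named list; recognised elements: `dhmp`, `dmp`, `peaks`
#'   (data.frames), `regions` (data.frame with chrom/start/end/fdr),
#'   `metagene` (named list of `metagene_profile`), `manifest` (list).
#' @param out_dir output directory.
#' @return Invisibly, the files written.
#' @export
write_results <- function(results, out_dir) {
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir))
    stop_ox("cannot create output directory %s", out_dir,
            class = "oxbspipe_io_error")
  written <- character(0)
  tsv <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    written <<- c(written, p)
  }
  for (nm in intersect(c("dhmp", "dmp", "peaks"), names(results)))
    tsv(results[[nm]], paste0(nm, ".tsv"))
  if (!is.null(results$regions)) {
    rg <- results$regions
    tsv(rg, "regions.tsv")
    p <- file.path(out_dir, "regions.bed")
    if (nrow(rg)) {
      score <- pmin(1000, round(-log10(pmax(rg$fdr, 1e-300)) * 100))
      bed <- data.frame(rg$chrom, rg$start, rg$end,
                        sprintf("region_%d", seq_len(nrow(rg))), score, ".")
    } else {
      bed <- data.frame(chrom = character(0), start = integer(0),
                        end = integer(0), name = character(0),
                        score = integer(0), strand = character(0))
    }
    utils::write.table(bed, p, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    written <- c(written, p)
  }
  for (nm in names(results$metagene %||% list())) {
    mp <- results$metagene[[nm]]
    tsv(cbind(gene_set = rownames(mp$mean), as.data.frame(mp$mean)),
        sprintf("metagene_%s.tsv", nm))
  }
  if (!is.null(results$manifest)) {
    p <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(results$manifest, p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
    written <- c(written, p)
  }
  invisible(written)
}
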