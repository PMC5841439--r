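# Transcript annotation container. Coordinates are 0-based half-open
# internally; GTF I/O converts from/to the 1-based inclusive convention.

new_genome_annotation <- function(genes) {
  structure(list(genes = genes), class = "genome_annotation")
}

#' Construct a genome annotation from per-transcript exon tables
#'
#' Builds the validated in-memory annotation used by all downstream stages.
#' Exon (and optional CDS) intervals are 0-based half-open.
#'
#' @param transcripts a `data.frame` with columns `gene_id`, `transcript_id`,
#'   `chrom`, `strand` (`"+"` or `"-"`), `start`, `end` (one row per exon,
#'   0-based half-open), and optionally `cds_start`, `cds_end` (constant
#'   within a transcript, `NA` for non-coding transcripts).
#' @return an object of class `genome_annotation`: a list of genes, each with
#'   `gene_id`, `chrom`, `strand` and a list of transcripts holding an exon
#'   matrix (`start`, `end`) plus an optional `cds` interval.
#' @export
genome_annotation <- function(transcripts) {
  required <- c("gene_id", "transcript_id", "chrom", "strand", "start", "end")
  missing <- setdiff(required, names(transcripts))
  if (length(missing))
    stop("missing columns: ", paste(missing, collapse = ", "))
  has_cds <- all(c("cds_start", "cds_end") %in% names(transcripts))
  genes <- list()
  for (gid in unique(transcripts$gene_id)) {
    gt <- transcripts[transcripts$gene_id == gid, , drop = FALSE]
    if (length(unique(gt$chrom)) != 1L || length(unique(gt$strand)) != 1L)
      stop("gene ", gid, ": transcripts must share chromosome and strand")
    txs <- list()
    for (tid in unique(gt$transcript_id)) {
      tt <- gt[gt$transcript_id == tid, , drop = FALSE]
      ex <- cbind(start = as.integer(tt$start), end = as.integer(tt$end))
      ex <- ex[order(ex[, 1L]), , drop = FALSE]
      validate_exons(ex, tid)
      cds <- NULL
      if (has_cds && !is.na(tt$cds_start[1L])) {
        cds <- c(as.integer(tt$cds_start[1L]), as.integer(tt$cds_end[1L]))
        if (cds[1L] < ex[1L, 1L] || cds[2L] > ex[nrow(ex), 2L])
          stop("transcript ", tid, ": CDS outside exonic span")
      }
      txs[[tid]] <- list(transcript_id = tid, exons = ex, cds = cds)
    }
    genes[[gid]] <- list(gene_id = gid, chrom = gt$chrom[1L],
                         strand = gt$strand[1L], transcripts = txs)
  }
  new_genome_annotation(genes)
}

validate_exons <- function(ex, tid) {
  if (nrow(ex) < 1L) stop("transcript ", tid, ": no exons")
  if (any(ex[, 2L] <= ex[, 1L]))
    stop("transcript ", tid, ": empty or inverted exon interval")
  if (nrow(ex) > 1L && any(ex[-1L, 1L] < ex[-nrow(ex), 2L]))
    stop("transcript ", tid, ": overlapping exons")
  invisible(ex)
}

#' Read a GTF file into a genome annotation
#'
#' Exon features (and CDS features, if present) carrying `gene_id` and
#' `transcript_id` attributes are assembled into transcripts; 1-based
#' inclusive GTF coordinates become 0-based half-open.
#'
#' @param path path to a GTF file.
#' @return a [genome_annotation()] object.
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  body <- !grepl("^#", lines) & nzchar(lines)
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nf < 9L)) {
    bad <- which(body)[which(nf < 9L)[1L]]
    stop("malformed GTF line ", bad, ": fewer than 9 tab-separated fields")
  }
  gr <- rtracklayer::import(path, format = "gtf")
  keep <- tolower(as.character(gr$type)) %in% c("exon", "cds")
  gr <- gr[keep]
  if (!length(gr)) stop("no exon features in ", path)
  if (is.null(gr$gene_id) || is.null(gr$transcript_id) ||
      anyNA(gr$gene_id) || anyNA(gr$transcript_id))
    stop("exon features must carry gene_id and transcript_id attributes")
  type <- tolower(as.character(gr$type))
  df <- data.frame(
    gene_id = gr$gene_id, transcript_id = gr$transcript_id,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr) - 1L, end = GenomicRanges::end(gr),
    type = type, stringsAsFactors = FALSE)
  ex <- df[df$type == "exon", , drop = FALSE]
  cds <- df[df$type == "cds", , drop = FALSE]
  if (nrow(cds)) {
    agg_lo <- tapply(cds$start, cds$transcript_id, min)
    agg_hi <- tapply(cds$end, cds$transcript_id, max)
    ex$cds_start <- as.integer(agg_lo[ex$transcript_id])
    ex$cds_end <- as.integer(agg_hi[ex$transcript_id])
  }
  genome_annotation(ex)
}

#' Write a genome annotation to GTF
#'
#' Inverse of [read_gtf()]: exon coordinates are written 1-based inclusive
#' and survive a read/write round trip exactly.
#'
#' @param annotation a `genome_annotation`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(annotation, path) {
  stopifnot(inherits(annotation, "genome_annotation"))
  rows <- list()
  for (g in annotation$genes) {
    for (tx in g$transcripts) {
      ex <- tx$exons
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = g$chrom, start = ex[, 1L], end = ex[, 2L],
        strand = g$strand, type = "exon", gene_id = g$gene_id,
        transcript_id = tx$transcript_id, stringsAsFactors = FALSE)
      if (!is.null(tx$cds))
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = g$chrom, start = tx$cds[1L], end = tx$cds[2L],
          strand = g$strand, type = "CDS", gene_id = g$gene_id,
          transcript_id = tx$transcript_id, stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    df$chrom, IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = df$strand, type = df$type, source = "spliceDAS",
    gene_id = df$gene_id, transcript_id = df$transcript_id)
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' @export
print.genome_annotation <- function(x, ...) {
  ntx <- sum(vapply(x$genes, function(g) length(g$transcripts), integer(1)))
  nex <- sum(vapply(x$genes, function(g)
    sum(vapply(g$transcripts, function(t) nrow(t$exons), integer(1))),
    integer(1)))
  cat("genome_annotation:", length(x$genes), "genes,", ntx, "transcripts,",
      nex, "exons\n")
  invisible(x)
}

# transcript-order exon matrix (row 1 = 5' end in transcript orientation)
tx_order <- function(exons, strand) {
  if (strand == "-") exons[rev(seq_len(nrow(exons))), , drop = FALSE]
  else exons
}
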