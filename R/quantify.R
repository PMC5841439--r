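# Junction-anchored isoform counting. A read is a set of aligned blocks
# (0-based half-open); gaps between consecutive blocks are splice junctions.
# Junction matching is exact; a block supports an exon body only when fully
# contained. Reads compatible with both isoforms of an event count for
# neither.

#' Construct an aligned-read set
#'
#' @param sample_id sample label applied to all reads.
#' @param chrom character vector, one chromosome per read.
#' @param blocks list of two-column integer matrices (`start`, `end`,
#'   0-based half-open), one per read, blocks sorted and non-overlapping.
#' @return an object of class `aligned_reads`.
#' @export
aligned_reads <- function(sample_id, chrom, blocks) {
  stopifnot(length(chrom) == length(blocks))
  for (b in blocks)
    if (!is.matrix(b) || ncol(b) != 2L || nrow(b) < 1L ||
        any(b[, 2L] <= b[, 1L]) ||
        (nrow(b) > 1L && any(b[-1L, 1L] < b[-nrow(b), 2L])))
      stop("read blocks must be non-empty, sorted and non-overlapping")
  structure(list(sample_id = sample_id, chrom = as.character(chrom),
                 blocks = blocks), class = "aligned_reads")
}

#' Read a BED12 file as aligned reads
#'
#' Block structure (columns 10-12) is expanded into per-read block matrices.
#'
#' @param path BED12 file path.
#' @param sample_id sample label for the file.
#' @return an [aligned_reads()] object.
#' @export
read_bed12 <- function(path, sample_id) {
  gr <- rtracklayer::import(path, format = "bed")
  n <- length(gr)
  chrom <- as.character(GenomicRanges::seqnames(gr))
  starts0 <- GenomicRanges::start(gr) - 1L
  blocks <- vector("list", n)
  bl <- gr$blocks
  for (i in seq_len(n)) {
    if (!is.null(bl) && length(bl[[i]])) {
      s <- starts0[i] + IRanges::start(bl[[i]]) - 1L
      e <- s + IRanges::width(bl[[i]])
    } else {
      s <- starts0[i]; e <- GenomicRanges::end(gr)[i]
    }
    blocks[[i]] <- cbind(start = as.integer(s), end = as.integer(e))
  }
  aligned_reads(sample_id, chrom, blocks)
}

#' Write aligned reads to BED12
#' @param reads an [aligned_reads()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed12 <- function(reads, path) {
  lines <- vapply(seq_along(reads$blocks), function(i) {
    b <- reads$blocks[[i]]
    cs <- b[1L, 1L]; ce <- b[nrow(b), 2L]
    paste(reads$chrom[i], cs, ce,
          paste0(reads$sample_id, "_r", i), 0L, "+", cs, ce, "0", nrow(b),
          paste0(paste(b[, 2L] - b[, 1L], collapse = ","), ","),
          paste0(paste(b[, 1L] - cs, collapse = ","), ","),
          sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

jkey <- function(chrom, a, b) paste0(chrom, ":", a, "-", b)
bkey <- jkey

# body intervals needed for counting: all annotated exons plus event-derived
# regions (A5SS/A3SS extensions, ME/AFE/ALE variable exons already exonic)
body_intervals <- function(annotation, events = NULL) {
  rows <- list()
  for (g in annotation$genes)
    for (tx in g$transcripts)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = g$chrom, start = tx$exons[, 1L], end = tx$exons[, 2L],
        stringsAsFactors = FALSE)
  if (!is.null(events) && nrow(events)) {
    for (i in seq_len(nrow(events))) {
      for (s in c(events$inclusion_chain[i], events$exclusion_chain[i],
                  events$variable_region[i])) {
        m <- chain_mat(s)
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = events$chrom[i], start = m[, 1L], end = m[, 2L],
          stringsAsFactors = FALSE)
      }
    }
  }
  df <- do.call(rbind, rows)
  df[!duplicated(paste0(df$chrom, ":", df$start, "-", df$end)), , drop = FALSE]
}

ir_intron_intervals <- function(events) {
  if (is.null(events) || !nrow(events)) return(NULL)
  ir <- events[events$event_type == "IR", , drop = FALSE]
  if (!nrow(ir)) return(NULL)
  m <- do.call(rbind, lapply(ir$variable_region, chain_mat))
  data.frame(chrom = rep(ir$chrom, vapply(ir$variable_region,
                                          function(s) nrow(chain_mat(s)),
                                          integer(1))),
             start = m[, 1L], end = m[, 2L], stringsAsFactors = FALSE)
}

#' Count reads over exons, junctions and retained introns
#'
#' A read supports junction `(a,b)` iff two consecutive blocks end exactly at
#' `a` and start exactly at `b`; it contributes to an exon's body count iff
#' at least one block lies entirely within the exon; it supports a retained
#' intron iff a block lies within the intron or a single-block read spans an
#' exon-intron boundary. Each read counts at most once per feature. Reads on
#' chromosomes absent from the annotation are skipped (counted in
#' `n_skipped`).
#'
#' @param reads an [aligned_reads()] object or a list of them (one per
#'   sample).
#' @param annotation a [genome_annotation()].
#' @param events optional `splice_events`; when supplied, event-derived
#'   regions (splice-site extensions, retained introns) join the feature
#'   index so that [assign_event_counts()] can resolve every event.
#' @return an object of class `feature_counts`: per sample, named counts for
#'   `junction`, `body` and `intron` features (keys `"chrom:start-end"`).
#' @export
count_features <- function(reads, annotation, events = NULL) {
  if (inherits(reads, "aligned_reads")) reads <- list(reads)
  chroms <- unique(vapply(annotation$genes, function(g) g$chrom, character(1)))
  bodies <- body_intervals(annotation, events)
  introns <- ir_intron_intervals(events)
  out <- list()
  for (rd in reads) {
    keep <- rd$chrom %in% chroms
    n_skipped <- sum(!keep)
    if (n_skipped) warning(n_skipped, " read(s) on unknown chromosomes skipped")
    blocks <- rd$blocks[keep]; chrom <- rd$chrom[keep]
    nb <- vapply(blocks, nrow, integer(1))
    # junction counts
    jc <- integer(0)
    if (length(blocks)) {
      jks <- unlist(lapply(seq_along(blocks), function(i) {
        b <- blocks[[i]]
        if (nrow(b) < 2L) return(character(0))
        unique(jkey(chrom[i], b[-nrow(b), 2L], b[-1L, 1L]))
      }))
      jc <- c(table(jks))
    }
    # flat block table
    if (length(blocks)) {
      flat <- data.frame(
        read = rep(seq_along(blocks), nb),
        chrom = rep(chrom, nb),
        start = unlist(lapply(blocks, function(b) b[, 1L])),
        end = unlist(lapply(blocks, function(b) b[, 2L])),
        single = rep(nb == 1L, nb), stringsAsFactors = FALSE)
    } else {
      flat <- data.frame(read = integer(), chrom = character(),
                         start = integer(), end = integer(),
                         single = logical())
    }
    bc <- count_within(flat, bodies)
    ic <- count_intron_support(flat, introns)
    out[[rd$sample_id]] <- list(junction = jc, body = bc, intron = ic,
                                n_skipped = n_skipped)
  }
  structure(out, class = "feature_counts")
}

count_within <- function(flat, bodies) {
  res <- integer(0)
  for (ch in unique(bodies$chrom)) {
    f <- flat[flat$chrom == ch, , drop = FALSE]
    b <- bodies[bodies$chrom == ch, , drop = FALSE]
    if (!nrow(f) || !nrow(b)) next
    q <- IRanges::IRanges(f$start + 1L, f$end)
    s <- IRanges::IRanges(b$start + 1L, b$end)
    ov <- IRanges::findOverlaps(q, s, type = "within")
    if (!length(ov)) next
    key <- bkey(ch, b$start[S4Vectors::subjectHits(ov)],
                b$end[S4Vectors::subjectHits(ov)])
    pair <- paste(f$read[S4Vectors::queryHits(ov)], key)
    res <- c(res, c(table(key[!duplicated(pair)])))
  }
  res
}

count_intron_support <- function(flat, introns) {
  if (is.null(introns) || !nrow(introns)) return(integer(0))
  res <- integer(0)
  for (ch in unique(introns$chrom)) {
    f <- flat[flat$chrom == ch, , drop = FALSE]
    it <- introns[introns$chrom == ch, , drop = FALSE]
    if (!nrow(f) || !nrow(it)) next
    q <- IRanges::IRanges(f$start + 1L, f$end)
    s <- IRanges::IRanges(it$start + 1L, it$end)
    ov <- IRanges::findOverlaps(q, s)
    if (!length(ov)) next
    qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
    m1 <- it$start[si]; m2 <- it$end[si]
    bs <- f$start[qi]; be <- f$end[qi]
    within <- bs >= m1 & be <= m2
    spans <- f$single[qi] & ((bs < m1 & be > m1) | (bs < m2 & be > m2))
    keep <- within | spans
    if (!any(keep)) next
    key <- jkey(ch, m1[keep], m2[keep])
    pair <- paste(f$read[qi][keep], key)
    res <- c(res, c(table(key[!duplicated(pair)])))
  }
  res
}

lookup <- function(counts, keys) {
  if (!length(counts)) return(0L)
  sum(counts[keys[keys %in% names(counts)]])
}

# (n_inc, n_exc) rules per event type; chain junction of a 2..3-exon chain
chain_junc_keys <- function(chrom, m) {
  if (nrow(m) < 2L) return(character(0))
  jkey(chrom, m[-nrow(m), 2L], m[-1L, 1L])
}

event_counts_one <- function(ev, fc) {
  inc <- chain_mat(ev$inclusion_chain)
  exc <- chain_mat(ev$exclusion_chain)
  var <- chain_mat(ev$variable_region)
  ch <- ev$chrom
  type <- ev$event_type
  if (type %in% c("ES", "ME")) {
    v <- inc[2L, ]
    n_inc <- lookup(fc$junction, chain_junc_keys(ch, inc)) +
      lookup(fc$body, bkey(ch, v[1L], v[2L]))
    if (type == "ES") {
      n_exc <- lookup(fc$junction, chain_junc_keys(ch, exc))
    } else {
      w <- exc[2L, ]
      n_exc <- lookup(fc$junction, chain_junc_keys(ch, exc)) +
        lookup(fc$body, bkey(ch, w[1L], w[2L]))
    }
  } else if (type %in% c("A5SS", "A3SS")) {
    n_inc <- lookup(fc$junction, chain_junc_keys(ch, inc)) +
      lookup(fc$body, bkey(ch, var[1L, 1L], var[1L, 2L]))
    n_exc <- lookup(fc$junction, chain_junc_keys(ch, exc))
  } else if (type == "IR") {
    n_inc <- lookup(fc$intron, jkey(ch, var[1L, 1L], var[1L, 2L]))
    n_exc <- lookup(fc$junction, chain_junc_keys(ch, exc))
  } else { # AFE / ALE
    vp <- var[1L, ]; vd <- var[2L, ]
    n_inc <- lookup(fc$body, bkey(ch, vp[1L], vp[2L])) +
      lookup(fc$junction, chain_junc_keys(ch, inc))
    n_exc <- lookup(fc$body, bkey(ch, vd[1L], vd[2L])) +
      lookup(fc$junction, chain_junc_keys(ch, exc))
  }
  c(n_inc = n_inc, n_exc = n_exc)
}

#' Assign per-event isoform-support counts
#'
#' Converts feature counts into per-event, per-sample counts of reads
#' supporting the inclusion (proximal) and exclusion (distal) isoforms,
#' using junction-anchored rules per event type.
#'
#' @param events a `splice_events` data.frame.
#' @param fcounts a `feature_counts` object from [count_features()].
#' @param groups named character vector mapping sample ids to group labels.
#' @return an `event_counts` data.frame with columns `event_id`,
#'   `sample_id`, `group`, `n_inc`, `n_exc`.
#' @export
assign_event_counts <- function(events, fcounts, groups) {
  samples <- names(fcounts)
  if (!all(samples %in% names(groups)))
    stop("every sample needs a group label")
  rows <- vector("list", nrow(events) * length(samples))
  k <- 0L
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    for (s in samples) {
      cnt <- event_counts_one(ev, fcounts[[s]])
      k <- k + 1L
      rows[[k]] <- data.frame(event_id = ev$event_id, sample_id = s,
                              group = unname(groups[s]),
                              n_inc = unname(cnt["n_inc"]),
                              n_exc = unname(cnt["n_exc"]),
                              stringsAsFactors = FALSE)
    }
  }
  ec <- do.call(rbind, rows)
  class(ec) <- c("event_counts", "data.frame")
  ec
}

#' Write an event count table to TSV
#' @param counts an `event_counts` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_event_counts <- function(counts, path) {
  write.table(as.data.frame(counts), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read an event count table from TSV
#' @param path path written by [write_event_counts()].
#' @return an `event_counts` data.frame.
#' @export
read_event_counts <- function(path) {
  ec <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  if (any(ec$n_inc < 0) || any(ec$n_exc < 0)) stop("negative counts")
  class(ec) <- c("event_counts", "data.frame")
  ec
}
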