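# Enumeration of minimal alternative-splicing events of the seven types
# (ES, A5SS, A3SS, ME, IR, AFE, ALE) by pairwise transcript comparison.
# Events are data.frame rows; exon chains are serialized "start-end,start-end"
# strings in 0-based half-open genomic coordinates.

EVENT_TYPES <- c("ES", "A5SS", "A3SS", "ME", "IR", "AFE", "ALE")

chain_str <- function(m) paste(paste0(m[, 1L], "-", m[, 2L]), collapse = ",")

#' Parse an exon-chain string into a two-column interval matrix
#' @param s chain string, e.g. `"100-200,300-350"`.
#' @return integer matrix with columns `start`, `end`.
#' @export
chain_mat <- function(s) {
  parts <- strsplit(strsplit(s, ",", fixed = TRUE)[[1L]], "-", fixed = TRUE)
  m <- matrix(as.integer(unlist(parts)), ncol = 2L, byrow = TRUE)
  colnames(m) <- c("start", "end")
  m
}

event_id_of <- function(type, chrom, strand, inc, exc) {
  paste0(type, ":", chrom, ":", strand, ":", chain_str(inc), "|",
         chain_str(exc))
}

make_event <- function(type, gene_id, chrom, strand, inc, exc, var) {
  data.frame(
    event_id = event_id_of(type, chrom, strand, inc, exc),
    gene_id = gene_id, event_type = type, chrom = chrom, strand = strand,
    inclusion_chain = chain_str(inc), exclusion_chain = chain_str(exc),
    variable_region = chain_str(var), stringsAsFactors = FALSE)
}

iv_eq <- function(a, b) a[1L] == b[1L] && a[2L] == b[2L]
iv_disjoint <- function(a, b) a[2L] <= b[1L] || b[2L] <= a[1L]
chain_len <- function(m) sum(m[, 2L] - m[, 1L])

# find row index of exon `iv` in exon matrix `m`, 0 if absent
find_exon <- function(m, iv) {
  hit <- which(m[, 1L] == iv[1L] & m[, 2L] == iv[2L])
  if (length(hit)) hit[1L] else 0L
}

# events from one ordered transcript pair (A, B exon matrices, genomic order)
pair_events <- function(A, B, gene_id, chrom, strand) {
  out <- list()
  add <- function(type, inc, exc, var)
    out[[length(out) + 1L]] <<- make_event(type, gene_id, chrom, strand,
                                           inc, exc, var)
  nA <- nrow(A); nB <- nrow(B)

  # ES: A carries U,V,D; B carries U,D adjacent
  if (nA >= 3L) for (i in 2L:(nA - 1L)) {
    U <- A[i - 1L, ]; V <- A[i, ]; D <- A[i + 1L, ]
    j <- find_exon(B, U)
    if (j > 0L && j < nB && iv_eq(B[j + 1L, ], D))
      add("ES", rbind(U, V, D), rbind(U, D), rbind(V))
  }

  # ME: shared flanks, one distinct non-overlapping internal exon each
  if (nA >= 3L && nB >= 3L) for (i in 2L:(nA - 1L)) for (j in 2L:(nB - 1L)) {
    if (iv_eq(A[i - 1L, ], B[j - 1L, ]) && iv_eq(A[i + 1L, ], B[j + 1L, ]) &&
        !iv_eq(A[i, ], B[j, ]) && iv_disjoint(A[i, ], B[j, ])) {
      U <- A[i - 1L, ]; D <- A[i + 1L, ]; V1 <- A[i, ]; V2 <- B[j, ]
      l1 <- V1[2L] - V1[1L]; l2 <- V2[2L] - V2[1L]
      # inclusion = chain with longer variable exon; tie -> smaller start
      first <- if (l1 > l2 || (l1 == l2 && V1[1L] < V2[1L])) TRUE else FALSE
      Vi <- if (first) V1 else V2; Ve <- if (first) V2 else V1
      add("ME", rbind(U, Vi, D), rbind(U, Ve, D), rbind(Vi, Ve))
    }
  }

  # IR: B retains the intron between consecutive exons of A
  if (nA >= 2L) for (i in seq_len(nA - 1L)) {
    E1 <- A[i, ]; E2 <- A[i + 1L, ]
    if (find_exon(B, c(E1[1L], E2[2L])) > 0L)
      add("IR", rbind(c(E1[1L], E2[2L])), rbind(E1, E2),
          rbind(c(E1[2L], E2[1L])))
  }

  # A5SS / A3SS: variation at one inner boundary of a shared intron
  if (nA >= 2L && nB >= 2L) for (i in seq_len(nA - 1L)) for (j in seq_len(nB - 1L)) {
    up_a <- A[i, ]; dn_a <- A[i + 1L, ]; up_b <- B[j, ]; dn_b <- B[j + 1L, ]
    # donor-side (genomic-left intron edge) variation
    if (up_a[1L] == up_b[1L] && up_a[2L] != up_b[2L] && iv_eq(dn_a, dn_b)) {
      long <- if (up_a[2L] > up_b[2L]) list(up_a, up_b) else list(up_b, up_a)
      type <- if (strand == "+") "A5SS" else "A3SS"
      add(type, rbind(long[[1L]], dn_a), rbind(long[[2L]], dn_a),
          rbind(c(long[[2L]][2L], long[[1L]][2L])))
    }
    # acceptor-side (genomic-right intron edge) variation
    if (iv_eq(up_a, up_b) && dn_a[1L] != dn_b[1L] && dn_a[2L] == dn_b[2L]) {
      long <- if (dn_a[1L] < dn_b[1L]) list(dn_a, dn_b) else list(dn_b, dn_a)
      type <- if (strand == "+") "A3SS" else "A5SS"
      add(type, rbind(up_a, long[[1L]]), rbind(up_a, long[[2L]]),
          rbind(c(long[[1L]][1L], long[[2L]][1L])))
    }
  }

  # AFE / ALE: distinct non-overlapping terminal exons, shared neighbor exon
  At <- tx_order(A, strand); Bt <- tx_order(B, strand)
  if (nA >= 2L && nB >= 2L) {
    # first exons (transcript orientation)
    fA <- At[1L, ]; fB <- Bt[1L, ]
    if (!iv_eq(fA, fB) && iv_disjoint(fA, fB) && iv_eq(At[2L, ], Bt[2L, ]))
      out[[length(out) + 1L]] <-
        terminal_event("AFE", fA, fB, At[2L, ], gene_id, chrom, strand)
    # last exons
    lA <- At[nA, ]; lB <- Bt[nB, ]
    if (!iv_eq(lA, lB) && iv_disjoint(lA, lB) &&
        iv_eq(At[nA - 1L, ], Bt[nB - 1L, ]))
      out[[length(out) + 1L]] <-
        terminal_event("ALE", lA, lB, At[nA - 1L, ], gene_id, chrom, strand)
  }
  out
}

# AFE/ALE: inclusion chain = proximal isoform (variable exon nearer the
# shared constitutive exon); ties broken by smaller genomic start
terminal_event <- function(type, v1, v2, shared, gene_id, chrom, strand) {
  gap <- function(v) {
    if (v[2L] <= shared[1L]) shared[1L] - v[2L] else v[1L] - shared[2L]
  }
  g1 <- gap(v1); g2 <- gap(v2)
  prox_first <- g1 < g2 || (g1 == g2 && v1[1L] < v2[1L])
  vp <- if (prox_first) v1 else v2
  vd <- if (prox_first) v2 else v1
  sort_chain <- function(v) {
    m <- rbind(v, shared)
    m[order(m[, 1L]), , drop = FALSE]
  }
  make_event(type, gene_id, chrom, strand, sort_chain(vp), sort_chain(vd),
             rbind(vp, vd))
}

#' Enumerate alternative-splicing events from an annotation
#'
#' Compares every transcript pair within each gene and extracts the minimal
#' events of the seven types: exon skipping (ES), alternative 5'/3' splice
#' sites (A5SS/A3SS), mutually exclusive exons (ME), intron retention (IR)
#' and alternative first/last exons (AFE/ALE). For ES/A5SS/A3SS/IR the
#' inclusion chain is the longer isoform; for ME it is the chain with the
#' longer variable exon; for AFE/ALE it is the proximal isoform. Duplicated
#' events arising from different transcript pairs are collapsed; the result
#' is sorted by chromosome, start and type, so output order is deterministic.
#'
#' @param annotation a [genome_annotation()].
#' @return a `data.frame` (class `splice_events`) with columns `event_id`,
#'   `gene_id`, `event_type`, `chrom`, `strand`, `inclusion_chain`,
#'   `exclusion_chain`, `variable_region`.
#' @export
enumerate_events <- function(annotation) {
  stopifnot(inherits(annotation, "genome_annotation"))
  all <- list()
  for (g in annotation$genes) {
    txs <- g$transcripts
    if (length(txs) < 2L) next
    for (i in seq_len(length(txs) - 1L)) for (j in (i + 1L):length(txs)) {
      A <- txs[[i]]$exons; B <- txs[[j]]$exons
      all <- c(all,
               pair_events(A, B, g$gene_id, g$chrom, g$strand),
               pair_events(B, A, g$gene_id, g$chrom, g$strand))
    }
  }
  if (!length(all)) {
    ev <- data.frame(event_id = character(), gene_id = character(),
                     event_type = character(), chrom = character(),
                     strand = character(), inclusion_chain = character(),
                     exclusion_chain = character(),
                     variable_region = character(), stringsAsFactors = FALSE)
    class(ev) <- c("splice_events", "data.frame")
    return(ev)
  }
  ev <- do.call(rbind, all)
  ev <- ev[!duplicated(ev$event_id), , drop = FALSE]
  start <- vapply(ev$inclusion_chain,
                  function(s) chain_mat(s)[1L, 1L], integer(1))
  ev <- ev[order(ev$chrom, start, ev$event_type, ev$event_id), , drop = FALSE]
  rownames(ev) <- NULL
  class(ev) <- c("splice_events", "data.frame")
  ev
}

#' Write events to TSV
#' @param events a `splice_events` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  write.table(as.data.frame(events), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read events from TSV
#' @param path path written by [write_events()].
#' @return a `splice_events` data.frame.
#' @export
read_events <- function(path) {
  ev <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   colClasses = "character")
  class(ev) <- c("splice_events", "data.frame")
  ev
}
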