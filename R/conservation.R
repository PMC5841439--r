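# Cross-species splicing conservation: homolog mapping, overlap enrichment,
# isoform sequence extraction and pairwise matching, and the per-event
# PSI-consistency call.

#' Read a HomoloGene-format flat file into a two-species homology map
#'
#' HomoloGene build format: tab-separated `group_id`, `taxonomy_id`,
#' `gene_id`, `gene_symbol`, (further columns ignored). A gene may belong to
#' at most one homology group.
#'
#' @param path flat file path.
#' @param tax_a,tax_b taxonomy ids of the two species (defaults: human 9606,
#'   mouse 10090).
#' @return a `homology_map` data.frame with columns `group_id`, `gene_a`,
#'   `gene_b`.
#' @export
read_homologene <- function(path, tax_a = 9606, tax_b = 10090) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1:4] <- c("group_id", "tax_id", "gene_id", "symbol")
  homology_map(df[df$tax_id == tax_a, c("group_id", "symbol")],
               df[df$tax_id == tax_b, c("group_id", "symbol")])
}

#' Construct a homology map from per-species (group, symbol) tables
#' @param a,b data.frames with columns `group_id`, `symbol`.
#' @return a `homology_map` data.frame (`group_id`, `gene_a`, `gene_b`).
#' @export
homology_map <- function(a, b) {
  names(a) <- names(b) <- c("group_id", "symbol")
  if (anyDuplicated(a$symbol) || anyDuplicated(b$symbol))
    stop("a gene may map to at most one homology group")
  a <- a[!duplicated(a$group_id), ]
  b <- b[!duplicated(b$group_id), ]
  m <- merge(a, b, by = "group_id", suffixes = c("_a", "_b"))
  out <- data.frame(group_id = m$group_id, gene_a = m$symbol_a,
                    gene_b = m$symbol_b, stringsAsFactors = FALSE)
  class(out) <- c("homology_map", "data.frame")
  out
}

#' Cross-species DAS gene overlap at the homology-group level
#'
#' The background is the set of homology groups whose members are expressed
#' in both species; `both` / `a_only` / `b_only` count groups whose member
#' genes carry DAS events in both, only the first, or only the second
#' species.
#'
#' @param das_genes_a,das_genes_b character vectors of DAS gene symbols per
#'   species.
#' @param homology a `homology_map`.
#' @param expressed_a,expressed_b expressed gene symbols per species.
#' @return a `venn_counts` list: `both`, `a_only`, `b_only`,
#'   `background_total`.
#' @export
shared_gene_sets <- function(das_genes_a, das_genes_b, homology,
                             expressed_a, expressed_b) {
  fix <- function(das, expressed, label) {
    extra <- setdiff(das, expressed)
    if (length(extra)) {
      warning(length(extra), " DAS gene(s) absent from the ", label,
              " expressed list; added")
      expressed <- c(expressed, extra)
    }
    expressed
  }
  expressed_a <- fix(das_genes_a, expressed_a, "species-a")
  expressed_b <- fix(das_genes_b, expressed_b, "species-b")
  bg <- homology[homology$gene_a %in% expressed_a &
                   homology$gene_b %in% expressed_b, , drop = FALSE]
  in_a <- bg$gene_a %in% das_genes_a
  in_b <- bg$gene_b %in% das_genes_b
  venn_counts(both = sum(in_a & in_b), a_only = sum(in_a & !in_b),
              b_only = sum(!in_a & in_b), background_total = nrow(bg))
}

#' Venn counts for the two-species DAS overlap
#' @param both,a_only,b_only,background_total non-negative counts with
#'   `both + a_only + b_only <= background_total`.
#' @return a `venn_counts` list.
#' @export
venn_counts <- function(both, a_only, b_only, background_total) {
  v <- list(both = both, a_only = a_only, b_only = b_only,
            background_total = background_total)
  if (any(unlist(v) < 0)) stop("venn counts must be non-negative")
  if (both + a_only + b_only > background_total)
    stop("venn counts exceed the background total")
  structure(v, class = "venn_counts")
}

#' One-sided Fisher test of DAS-gene overlap enrichment
#'
#' Tests whether homology groups with DAS events in species a are enriched
#' for DAS events in species b, on the 2x2 table
#' `[[both, a_only], [b_only, background - both - a_only - b_only]]`.
#'
#' @param venn a [venn_counts()] object.
#' @return list with `odds_ratio` (conditional MLE) and `p` (one-sided,
#'   greater).
#' @export
overlap_enrichment <- function(venn) {
  stopifnot(inherits(venn, "venn_counts"))
  neither <- venn$background_total - venn$both - venn$a_only - venn$b_only
  if (neither < 0) stop("negative derived cell")
  tab <- matrix(c(venn$both, venn$a_only, venn$b_only, neither), 2L, 2L,
                byrow = TRUE)
  ft <- fisher.test(tab, alternative = "greater")
  list(odds_ratio = unname(ft$estimate), p = ft$p.value)
}

# --- isoform sequence extraction ------------------------------------------

# transcript-coordinate of a genomic position (0-based, transcript orient.)
tx_coord <- function(exons, strand, gpos) {
  ex <- tx_order(exons, strand)
  off <- 0L
  for (i in seq_len(nrow(ex))) {
    s <- ex[i, 1L]; e <- ex[i, 2L]
    if (gpos >= s && gpos < e) {
      within <- if (strand == "+") gpos - s else e - 1L - gpos
      return(off + within)
    }
    off <- off + (e - s)
  }
  NA_integer_
}

# chain rows form a consecutive run of tx exons?
chain_in_transcript <- function(chain, exons) {
  idx <- vapply(seq_len(nrow(chain)),
                function(i) find_exon(exons, chain[i, ]), integer(1))
  all(idx > 0L) && all(diff(idx) == 1L)
}

chain_seq <- function(chain, chromseq, strand) {
  parts <- lapply(seq_len(nrow(chain)), function(i)
    Biostrings::subseq(chromseq, chain[i, 1L] + 1L, chain[i, 2L]))
  s <- do.call(Biostrings::xscat, parts)
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  s
}

translate_chain <- function(chain, tx, chromseq, strand) {
  if (is.null(tx$cds)) return(NULL)
  span <- c(min(chain[, 1L]), max(chain[, 2L]))
  if (span[1L] < tx$cds[1L] || span[2L] > tx$cds[2L]) return(NULL)
  cds5 <- if (strand == "+") tx$cds[1L] else tx$cds[2L] - 1L
  ch5 <- if (strand == "+") span[1L] else span[2L] - 1L
  off <- tx_coord(tx$exons, strand, ch5) - tx_coord(tx$exons, strand, cds5)
  if (is.na(off) || off < 0L) return(NULL)
  nt <- chain_seq(chain, chromseq, strand)
  trim <- (3L - off %% 3L) %% 3L
  if (length(nt) - trim < 3L) return(NULL)
  cod <- Biostrings::subseq(nt, trim + 1L,
                            trim + ((length(nt) - trim) %/% 3L) * 3L)
  aa <- Biostrings::translate(Biostrings::DNAString(as.character(cod)),
                              if.fuzzy.codon = "X")
  aa_chr <- as.character(aa)
  if (grepl("\\*", substr(aa_chr, 1L, nchar(aa_chr) - 1L))) {
    warning("internal stop codon in annotated frame; using nucleotide")
    return(NULL)
  }
  sub("\\*$", "", aa_chr)
}

#' Extract the two isoform sequences covering a splicing event
#'
#' Concatenates the exon sequences of the inclusion and exclusion chains
#' (reverse-complemented for minus-strand genes, so sequences read in
#' transcript orientation). When the event region lies within the annotated
#' CDS on both isoforms, both sequences are additionally translated in the
#' annotated frame and the alphabet is `"protein"`; otherwise the alphabet
#' is `"nucleotide"`. An internal stop codon triggers a fallback to
#' nucleotide with a warning.
#'
#' @param event one row of a `splice_events` data.frame.
#' @param genome a named [Biostrings::DNAStringSet] of chromosome sequences.
#' @param annotation the [genome_annotation()] the event came from.
#' @return list with `inclusion`, `exclusion` (character sequences in the
#'   reported alphabet), `alphabet`, and `nucleotide` (the untranslated
#'   pair, always present).
#' @export
extract_isoform_sequences <- function(event, genome, annotation) {
  if (is.data.frame(event)) event <- as.list(event[1L, ])
  chrom <- event$chrom
  if (!chrom %in% names(genome)) stop("chromosome ", chrom, " not in FASTA")
  chromseq <- genome[[chrom]]
  inc <- chain_mat(event$inclusion_chain)
  exc <- chain_mat(event$exclusion_chain)
  if (max(inc[, 2L], exc[, 2L]) > length(chromseq))
    stop("event span outside contig ", chrom)
  strand <- event$strand
  nt_inc <- as.character(chain_seq(inc, chromseq, strand))
  nt_exc <- as.character(chain_seq(exc, chromseq, strand))
  gene <- annotation$genes[[event$gene_id]]
  prot <- NULL
  if (!is.null(gene)) {
    find_tx <- function(chain) {
      for (tx in gene$transcripts)
        if (chain_in_transcript(chain, tx$exons)) return(tx)
      NULL
    }
    tx_i <- find_tx(inc); tx_e <- find_tx(exc)
    if (!is.null(tx_i) && !is.null(tx_e)) {
      aa_i <- translate_chain(inc, tx_i, chromseq, strand)
      aa_e <- translate_chain(exc, tx_e, chromseq, strand)
      if (!is.null(aa_i) && !is.null(aa_e) && nzchar(aa_i) && nzchar(aa_e))
        prot <- list(inclusion = aa_i, exclusion = aa_e)
    }
  }
  if (!is.null(prot))
    list(inclusion = prot$inclusion, exclusion = prot$exclusion,
         alphabet = "protein",
         nucleotide = list(inclusion = nt_inc, exclusion = nt_exc))
  else
    list(inclusion = nt_inc, exclusion = nt_exc, alphabet = "nucleotide",
         nucleotide = list(inclusion = nt_inc, exclusion = nt_exc))
}

# --- isoform matching ------------------------------------------------------

#' Global-alignment identity between two sequences
#'
#' Needleman-Wunsch with affine gaps (BLOSUM62 for protein; match +2 /
#' mismatch -1 for nucleotide; gap opening 10, extension 0.5). Identity is
#' matches over aligned columns, excluding terminal gap columns.
#'
#' @param a,b character sequences.
#' @param alphabet `"nucleotide"` or `"protein"`.
#' @return identity in `[0, 1]`.
#' @export
align_identity <- function(a, b, alphabet = c("nucleotide", "protein")) {
  alphabet <- match.arg(alphabet)
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  if (alphabet == "protein") {
    submat <- get_blosum62()
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b),
      substitutionMatrix = submat, gapOpening = 10, gapExtension = 0.5,
      type = "global")
  } else {
    submat <- Biostrings::nucleotideSubstitutionMatrix(
      match = 2, mismatch = -1, baseOnly = FALSE)
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(a), Biostrings::DNAString(b),
      substitutionMatrix = submat, gapOpening = 10, gapExtension = 0.5,
      type = "global")
  }
  p <- strsplit(as.character(Biostrings::pattern(pa)), "")[[1L]]
  s <- strsplit(as.character(Biostrings::subject(pa)), "")[[1L]]
  nongap <- which(p != "-" & s != "-")
  cols <- nongap[1L]:nongap[length(nongap)]
  mean(p[cols] == s[cols] & p[cols] != "-")
}

get_blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' Label cross-species isoform conservation
#'
#' Aligns the four cross-species isoform pairings and picks the pairing
#' (straight: inclusion-inclusion and exclusion-exclusion; crossed:
#' inclusion-exclusion both ways) with the higher summed identity. The label
#' is `both` if the straight pairing wins with both identities at or above
#' the threshold, `cross_matched` if the crossed pairing wins likewise,
#' `partial` if exactly one pair of the winning assignment reaches the
#' threshold, and `none` otherwise.
#'
#' @param seqs_a,seqs_b lists with `inclusion`, `exclusion`, `alphabet`
#'   (and `nucleotide` fallback pair), as returned by
#'   [extract_isoform_sequences()]. When alphabets differ the nucleotide
#'   sequences are compared.
#' @param identity_threshold minimum per-pair identity (default 0.5).
#' @return an `isoform_conservation` list: `label`, `identities` (named
#'   vector of the four pairwise identities), `pairing` (`straight` or
#'   `crossed`).
#' @export
match_isoforms <- function(seqs_a, seqs_b, identity_threshold = 0.5) {
  if (!is.null(seqs_a$alphabet) && !is.null(seqs_b$alphabet) &&
      seqs_a$alphabet != seqs_b$alphabet) {
    seqs_a <- c(seqs_a$nucleotide, alphabet = "nucleotide")
    seqs_b <- c(seqs_b$nucleotide, alphabet = "nucleotide")
  }
  alphabet <- if (identical(seqs_a$alphabet, "protein")) "protein"
              else "nucleotide"
  ids <- c(
    inc_inc = align_identity(seqs_a$inclusion, seqs_b$inclusion, alphabet),
    exc_exc = align_identity(seqs_a$exclusion, seqs_b$exclusion, alphabet),
    inc_exc = align_identity(seqs_a$inclusion, seqs_b$exclusion, alphabet),
    exc_inc = align_identity(seqs_a$exclusion, seqs_b$inclusion, alphabet))
  straight <- ids["inc_inc"] + ids["exc_exc"]
  crossed <- ids["inc_exc"] + ids["exc_inc"]
  pairing <- if (straight >= crossed) "straight" else "crossed"
  win <- if (pairing == "straight") ids[c("inc_inc", "exc_exc")]
         else ids[c("inc_exc", "exc_inc")]
  n_ok <- sum(win >= identity_threshold)
  label <- if (n_ok == 2L) {
    if (pairing == "straight") "both" else "cross_matched"
  } else if (n_ok == 1L) "partial" else "none"
  structure(list(label = label, identities = ids, pairing = pairing),
            class = "isoform_conservation")
}

#' PSI-consistency call for a homologous event pair
#'
#' An event pair is consistent (`"Y"`) iff the two dPSI values have the same
#' non-zero sign and the isoform-conservation label is `"both"`; a
#' cross-matched pair is never consistent even when the signs agree. A zero
#' dPSI is sign-indeterminate and yields `"N"`. Vectorized.
#'
#' @param dpsi_a,dpsi_b dPSI in the two species.
#' @param label isoform-conservation label(s) (`"both"`, `"cross_matched"`,
#'   `"partial"`, `"none"`) or `isoform_conservation` object(s).
#' @return character vector of `"Y"` / `"N"`.
#' @export
call_psi_consistency <- function(dpsi_a, dpsi_b, label) {
  if (inherits(label, "isoform_conservation")) label <- label$label
  ifelse(sign(dpsi_a) == sign(dpsi_b) & dpsi_a != 0 & dpsi_b != 0 &
           label == "both", "Y", "N")
}

#' Summarize conserved event calls
#'
#' @param calls a data.frame with columns `dpsi_a`, `dpsi_b` and
#'   `psi_consistency` (`"Y"`/`"N"`), e.g. from [table1_fixture()] plus
#'   [call_psi_consistency()].
#' @param large_dpsi threshold for "largely spliced" (default 0.10; strict,
#'   so `|dPSI| = 0.100` exactly does not pass).
#' @return list with `n_consistent` (count of Y) and `n_large_both`
#'   (Y events with `|dPSI| > large_dpsi` in both species).
#' @export
summarize_conserved <- function(calls, large_dpsi = 0.10) {
  if (!nrow(calls)) return(list(n_consistent = 0L, n_large_both = 0L))
  y <- calls$psi_consistency == "Y"
  large <- y & abs(calls$dpsi_a) > large_dpsi & abs(calls$dpsi_b) > large_dpsi
  list(n_consistent = sum(y), n_large_both = sum(large))
}

#' Conserved-event table packaged with the package
#'
#' The 24 mouse-human exon-skipping event records (gene pair, dPSI in each
#' species, isoform-conservation label, printed consistency call) used by
#' the conservation examples and tests.
#'
#' @return a data.frame with columns `gene_a` (human), `gene_b` (mouse),
#'   `dpsi_a`, `dpsi_b`, `conservation`, `psi_consistency_printed`.
#' @export
table1_fixture <- function() {
  path <- system.file("extdata", "conserved_events_fixture.tsv",
                      package = "spliceDAS", mustWork = TRUE)
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
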