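test_that("overlap enrichment matches the hypergeometric summation oracle", {
  # [[5,0],[0,5]]: only the all-or-nothing table is as extreme
  v <- venn_counts(5, 0, 0, 10)
  r <- overlap_enrichment(v)
  expect_equal(r$p, 1 / choose(10, 5), tolerance = 1e-10)
  expect_equal(r$p, fisher_oracle(5, 0, 0, 5), tolerance = 1e-10)
  # no overlap with small margins: no evidence of enrichment
  r0 <- overlap_enrichment(venn_counts(0, 2, 2, 100))
  expect_gt(r0$p, 0.99)
  # random valid tables against the oracle
  set.seed(9)
  for (i in 1:25) {
    N <- sample(20:200, 1L)
    a <- sample(0:10, 1L); b <- sample(0:40, 1L); c_ <- sample(0:40, 1L)
    if (a + b + c_ > N) next
    r <- overlap_enrichment(venn_counts(a, b, c_, N))
    o <- fisher_oracle(a, b, c_, N - a - b - c_)
    expect_equal(r$p, o, tolerance = 1e-6 * max(o, 1e-12))
  }
})

test_that("venn counts validate their invariants", {
  expect_error(venn_counts(5, 5, 5, 10), "exceed")
  expect_error(venn_counts(-1, 0, 0, 10), "non-negative")
})

test_that("gene-level sharing counts homology groups, not symbols", {
  hm <- homology_map(
    data.frame(group_id = 1:5, symbol = paste0("A", 1:5)),
    data.frame(group_id = 1:5, symbol = paste0("B", 1:5)))
  v <- shared_gene_sets(c("A1", "A2"), c("B2", "B3"), hm,
                        paste0("A", 1:5), paste0("B", 1:5))
  expect_equal(v$both, 1L)
  expect_equal(v$a_only, 1L)
  expect_equal(v$b_only, 1L)
  expect_equal(v$background_total, 5L)
  # identical lists give a_only = b_only = 0
  v2 <- shared_gene_sets(c("A1", "A2"), c("B1", "B2"), hm,
                         paste0("A", 1:5), paste0("B", 1:5))
  expect_equal(c(v2$both, v2$a_only, v2$b_only), c(2L, 0L, 0L))
  # DAS gene missing from the expressed list warns and is added
  expect_warning(
    shared_gene_sets("A1", "B9", homology_map(
      data.frame(group_id = 1:2, symbol = c("A1", "A9")),
      data.frame(group_id = 1:2, symbol = c("B1", "B9"))),
      "A1", "B1"), "absent")
})

test_that("HomoloGene flat files map symbols in both directions", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("3\t9606\t34\tACADM\t4557231\tNP_000007.1",
               "3\t10090\t11364\tAcadm\t6680618\tNP_031408.1",
               "5\t9606\t37\tACADVL\t4557235\tNP_000009.1",
               "5\t10090\t11370\tAcadvl\t6680624\tNP_059062.1"), f)
  hm <- read_homologene(f)
  expect_equal(nrow(hm), 2L)
  expect_equal(hm$gene_b[hm$gene_a == "ACADM"], "Acadm")
})

test_that("isoform sequences concatenate exons and honor strand", {
  ev <- data.frame(event_id = "e", gene_id = "g1", event_type = "ES",
                   chrom = "chr1", strand = "+",
                   inclusion_chain = "0-3,5-8,10-13",
                   exclusion_chain = "0-3,10-13",
                   variable_region = "5-8", stringsAsFactors = FALSE)
  genome <- Biostrings::DNAStringSet(c(chr1 = "ATGGGAAAGGTGACC"))
  ann <- genome_annotation(data.frame(
    gene_id = "g1", transcript_id = rep(c("t1", "t2"), c(3L, 2L)),
    chrom = "chr1", strand = "+",
    start = c(0L, 5L, 10L, 0L, 10L), end = c(3L, 8L, 13L, 3L, 13L)))
  sq <- extract_isoform_sequences(ev, genome, ann)
  expect_equal(sq$inclusion, "ATGAAATGA")
  expect_equal(sq$exclusion, "ATGTGA")
  expect_equal(sq$alphabet, "nucleotide")
  # minus strand: reverse complement of the concatenation
  ev$strand <- "-"
  ann2 <- genome_annotation(data.frame(
    gene_id = "g1", transcript_id = rep(c("t1", "t2"), c(3L, 2L)),
    chrom = "chr1", strand = "-",
    start = c(0L, 5L, 10L, 0L, 10L), end = c(3L, 8L, 13L, 3L, 13L)))
  sq2 <- extract_isoform_sequences(ev, genome, ann2)
  expect_equal(sq2$inclusion, "TCATTTCAT")  # revcomp of ATGAAATGA
  expect_equal(sq2$exclusion,
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString("ATGTGA"))))
})

test_that("coding events translate in the annotated frame", {
  # CDS covers the whole transcript; V is one codon, so the inclusion
  # protein carries exactly one extra residue
  genome <- Biostrings::DNAStringSet(c(
    chr1 = paste0("ATGGTT", "AAA", "GGCTAA")))
  ann <- genome_annotation(data.frame(
    gene_id = "g1", transcript_id = rep(c("t1", "t2"), c(3L, 2L)),
    chrom = "chr1", strand = "+",
    start = c(0L, 6L, 9L, 0L, 9L), end = c(6L, 9L, 15L, 6L, 15L),
    cds_start = c(0L, 0L, 0L, 0L, 0L), cds_end = c(15L, 15L, 15L, 15L, 15L)))
  ev <- enumerate_events(ann)
  sq <- extract_isoform_sequences(ev[1L, ], genome, ann)
  expect_equal(sq$alphabet, "protein")
  expect_equal(nchar(sq$inclusion), nchar(sq$exclusion) + 1L)
  expect_equal(sq$inclusion, "MVKG")
  expect_equal(sq$exclusion, "MVG")
})

test_that("isoform matching labels straight, crossed and degenerate pairs", {
  a <- list(inclusion = "ATGGTTAAAGGCTAAATG", exclusion = "ATGGTTGGCTAA",
            alphabet = "nucleotide")
  ident <- match_isoforms(a, a)
  expect_equal(ident$label, "both")
  expect_equal(unname(ident$identities[c("inc_inc", "exc_exc")]), c(1, 1))
  swapped <- list(inclusion = a$exclusion, exclusion = a$inclusion,
                  alphabet = "nucleotide")
  expect_equal(match_isoforms(a, swapped)$label, "cross_matched")
  expect_error(match_isoforms(a, list(inclusion = "", exclusion = "A",
                                      alphabet = "nucleotide")), "empty")
})

test_that("matching is symmetric in species order under divergence", {
  set.seed(33)
  cfg <- sim_config(seed = 33, events_per_type = 2, sub_rate = 0.1,
                    conserved_frac = 1, crossed_frac = 0)
  sp_a <- simulate_annotation(cfg)
  sp_b <- simulate_two_species(cfg, sp_a)
  ev_a <- enumerate_events(sp_a$annotation)
  ev_b <- enumerate_events(sp_b$annotation)
  es <- sp_b$classes[sp_b$classes$event_a %in%
                       ev_a$event_id[ev_a$event_type == "ES"], ]
  for (i in seq_len(nrow(es))) {
    sa <- extract_isoform_sequences(ev_a[ev_a$event_id == es$event_a[i], ],
                                    sp_a$genome, sp_a$annotation)
    sb <- extract_isoform_sequences(ev_b[ev_b$event_id == es$event_b[i], ],
                                    sp_b$genome, sp_b$annotation)
    expect_equal(match_isoforms(sa, sb)$label, match_isoforms(sb, sa)$label)
  }
})

test_that("divergence simulation recovers planted conservation classes", {
  hits <- c(conserved = 0L, cross_matched = 0L, total_c = 0L, total_x = 0L)
  for (seed in 1:8) {
    cfg <- sim_config(seed = seed, events_per_type = 3, sub_rate = 0.1,
                      conserved_frac = 0.5, crossed_frac = 0.5)
    sp_a <- simulate_annotation(cfg)
    sp_b <- simulate_two_species(cfg, sp_a)
    ev_a <- enumerate_events(sp_a$annotation)
    ev_b <- enumerate_events(sp_b$annotation)
    es <- sp_b$classes[sp_b$classes$event_a %in%
                         ev_a$event_id[ev_a$event_type == "ES"], ]
    for (i in seq_len(nrow(es))) {
      sa <- extract_isoform_sequences(ev_a[ev_a$event_id == es$event_a[i], ],
                                      sp_a$genome, sp_a$annotation)
      sb <- extract_isoform_sequences(ev_b[ev_b$event_id == es$event_b[i], ],
                                      sp_b$genome, sp_b$annotation)
      lab <- match_isoforms(sa, sb)$label
      if (es$class[i] == "conserved") {
        hits["total_c"] <- hits["total_c"] + 1L
        hits["conserved"] <- hits["conserved"] + (lab == "both")
      } else if (es$class[i] == "cross_matched") {
        hits["total_x"] <- hits["total_x"] + 1L
        hits["cross_matched"] <- hits["cross_matched"] + (lab == "cross_matched")
      }
    }
  }
  expect_gte(hits[["conserved"]], hits[["total_c"]] - 1L)
  expect_gte(hits[["cross_matched"]], hits[["total_x"]] - 1L)
  expect_gt(hits[["total_c"]], 3L)
  expect_gt(hits[["total_x"]], 3L)
})

test_that("PSI consistency demands matching signs and straight conservation", {
  expect_equal(call_psi_consistency(0.186, 0.198, "both"), "Y")    # EXOC1
  expect_equal(call_psi_consistency(-0.060, 0.091, "both"), "N")   # AXL
  expect_equal(call_psi_consistency(-0.180, -0.078, "cross_matched"), "N") # DMKN
  expect_equal(call_psi_consistency(0, 0.2, "both"), "N")
})

test_that("summaries count consistent and largely spliced events strictly", {
  tab <- table1_fixture()
  tab$psi_consistency <- call_psi_consistency(tab$dpsi_a, tab$dpsi_b,
                                              tab$conservation)
  s <- summarize_conserved(tab, large_dpsi = 0.10)
  expect_equal(s$n_consistent, 18L)
  expect_equal(s$n_large_both, 8L)
  empty <- summarize_conserved(tab[0, ])
  expect_equal(c(empty$n_consistent, empty$n_large_both), c(0L, 0L))
})
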