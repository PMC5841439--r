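# End-to-end orchestration over synthetic two-species data: simulate,
# enumerate, count, test, conserve, compare signatures, enrich; write TSVs
# and a run manifest with file hashes so reruns are verifiably identical.

#' Run the full analysis pipeline on simulated two-species data
#'
#' Executes the stages in dependency order: simulate species-a annotation
#' and counts, enumerate events, DAS testing; simulate and analyze the
#' homologous species b; cross-species gene overlap and isoform-level
#' conservation calls; count-level splicing-factor signature comparison;
#' term enrichment of the species-a DAS genes. All outputs are TSV files in
#' `out_dir`, listed with MD5 hashes in `manifest.tsv`. Rerunning with the
#' same configuration reproduces identical files.
#'
#' @param out_dir output directory (created if needed).
#' @param config a [sim_config()]; `config$seed` fixes the whole run.
#' @param dpsi_threshold,q_threshold DAS significance thresholds.
#' @param large_dpsi threshold for the "largely spliced" tally.
#' @param identity_threshold isoform-conservation identity threshold.
#' @param alpha,rule candidate-SF call parameters (see
#'   [compare_signatures()]).
#' @return invisibly, a list with the manifest data.frame and the main
#'   in-memory results (`das_a`, `das_b`, `venn`, `enrichment_p`,
#'   `conservation`, `comparisons`, `enrichment`).
#' @export
run_pipeline <- function(out_dir, config = sim_config(),
                         dpsi_threshold = 0.05, q_threshold = 0.05,
                         large_dpsi = 0.10, identity_threshold = 0.5,
                         alpha = 0.05, rule = "both") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(out_dir, f)
  log_msg <- function(...) message(format(Sys.time(), "%H:%M:%S "), ...)

  log_msg("simulating species a")
  sp_a <- simulate_annotation(config, gene_prefix = "GA")
  write_gtf(sp_a$annotation, pth("species_a.gtf"))
  Biostrings::writeXStringSet(sp_a$genome, pth("species_a.fa"))
  ev_a <- enumerate_events(sp_a$annotation)
  write_events(ev_a, pth("events_a.tsv"))

  log_msg("DAS analysis, species a")
  sim_a <- simulate_counts(config, ev_a)
  write_event_counts(sim_a$counts, pth("counts_a.tsv"))
  das_a <- das_test(sim_a$counts, "case", "control", events = ev_a,
                    dpsi_threshold = dpsi_threshold,
                    q_threshold = q_threshold)
  write_das(das_a, pth("das_a.tsv"))

  log_msg("simulating and analyzing species b")
  sp_b <- simulate_two_species(config, sp_a)
  write_gtf(sp_b$annotation, pth("species_b.gtf"))
  Biostrings::writeXStringSet(sp_b$genome, pth("species_b.fa"))
  ev_b <- enumerate_events(sp_b$annotation)
  write_events(ev_b, pth("events_b.tsv"))
  # differential splicing is planted on the exon-skipping events, whose
  # conservation classes and dPSI signs are fixed by the homology truth
  es_cls <- sp_b$classes[grepl("^ES:", sp_b$classes$event_a), , drop = FALSE]
  planted_b <- data.frame(event_id = es_cls$event_b,
                          delta = config$effect * es_cls$sign_b)
  sim_b <- simulate_counts(config, ev_b, planted = planted_b, stream = 1L)
  planted_a <- data.frame(event_id = es_cls$event_a,
                          delta = config$effect * es_cls$sign_a)
  sim_a2 <- simulate_counts(config, ev_a, planted = planted_a, stream = 2L)
  das_a2 <- das_test(sim_a2$counts, "case", "control", events = ev_a,
                     dpsi_threshold = dpsi_threshold,
                     q_threshold = q_threshold)
  das_b <- das_test(sim_b$counts, "case", "control", events = ev_b,
                    dpsi_threshold = dpsi_threshold,
                    q_threshold = q_threshold)
  write_das(das_b, pth("das_b.tsv"))

  log_msg("conservation analysis")
  das_genes_a <- unique(das_a2$gene_id[das_a2$significant])
  das_genes_b <- unique(das_b$gene_id[das_b$significant])
  all_a <- unique(ev_a$gene_id); all_b <- unique(ev_b$gene_id)
  venn <- shared_gene_sets(das_genes_a, das_genes_b, sp_b$homology,
                           all_a, all_b)
  enr <- overlap_enrichment(venn)
  writeLines(paste0("both\t", venn$both, "\na_only\t", venn$a_only,
                    "\nb_only\t", venn$b_only, "\nbackground\t",
                    venn$background_total, "\nfisher_p\t", enr$p),
             pth("venn.tsv"))
  cons <- conservation_calls(sp_a, sp_b, ev_a, ev_b, das_a2, das_b,
                             identity_threshold)
  write.table(cons, pth("conserved.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  log_msg("splicing-factor signature comparison")
  sf <- simulate_sf_perturbations(config, ev_a)
  comparisons <- list()
  for (s in seq_len(nrow(sf$meta))) {
    sfg <- sf$meta$sf_gene[s]
    das_p <- das_test(sf$perturb_counts[[sfg]], "case", "control",
                      events = ev_a)
    sig_p <- perturbation_signature(das_p, sf$meta$direction[s],
                                    dataset = sf$meta$dataset_id[s],
                                    sf_gene = sfg)
    dirn <- sf_direction(sf$expression, sfg,
                         grep("^case_", colnames(sf$expression)),
                         grep("^ctrl_", colnames(sf$expression)))
    das_d <- das_test(sf$disease_counts, "case", "control", events = ev_a)
    sig_d <- disease_signature(das_d, dirn, sf_gene = sfg)
    if (is.null(sig_d)) next
    comparisons[[sfg]] <- compare_signatures(sig_p, sig_d, alpha = alpha,
                                             rule = rule)
  }
  comp_df <- do.call(rbind, lapply(comparisons, function(x)
    data.frame(sf_gene = x$sf_gene, dataset = x$dataset, n_pp = x$n_pp,
               n_mm = x$n_mm, p_pp = x$p_pp, p_mm = x$p_mm,
               candidate = x$candidate, stringsAsFactors = FALSE)))
  write.table(comp_df, pth("sf_comparisons.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  log_msg("term enrichment")
  fg <- das_genes_a
  if (!length(fg)) fg <- all_a[1L]
  tm <- simulate_terms(config, fg, all_a)
  enrich_res <- enrich(fg, all_a, tm$terms)
  write.table(as.data.frame(enrich_res), pth("enrichment.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  files <- sort(setdiff(list.files(out_dir), "manifest.tsv"))
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(out_dir, files))),
    seed = config$seed, stringsAsFactors = FALSE)
  write.table(manifest, pth("manifest.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(list(manifest = manifest, das_a = das_a2, das_b = das_b,
                 venn = venn, enrichment_p = enr$p, conservation = cons,
                 comparisons = comparisons, enrichment = enrich_res))
}

# per-homolog-pair conservation calls for the ES events of both species
conservation_calls <- function(sp_a, sp_b, ev_a, ev_b, das_a, das_b,
                               identity_threshold) {
  cls <- sp_b$classes[sp_b$classes$event_a %in%
                        ev_a$event_id[ev_a$event_type == "ES"], ,
                      drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(cls))) {
    ea <- ev_a[ev_a$event_id == cls$event_a[i], ]
    eb <- ev_b[ev_b$event_id == cls$event_b[i], ]
    if (!nrow(ea) || !nrow(eb)) next
    da <- das_a[das_a$event_id == cls$event_a[i], ]
    db <- das_b[das_b$event_id == cls$event_b[i], ]
    if (!nrow(da) || !nrow(db)) next
    sq_a <- extract_isoform_sequences(ea, sp_a$genome, sp_a$annotation)
    sq_b <- extract_isoform_sequences(eb, sp_b$genome, sp_b$annotation)
    mi <- match_isoforms(sq_a, sq_b, identity_threshold)
    rows[[length(rows) + 1L]] <- data.frame(
      gene_a = cls$gene_a[i], gene_b = cls$gene_b[i],
      dpsi_a = da$delta_psi, dpsi_b = db$delta_psi,
      isoform_conservation = mi$label,
      psi_consistency = call_psi_consistency(da$delta_psi, db$delta_psi,
                                             mi$label),
      planted_class = cls$class[i], stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(gene_a = character(), gene_b = character(),
                      dpsi_a = numeric(), dpsi_b = numeric(),
                      isoform_conservation = character(),
                      psi_consistency = character(),
                      planted_class = character()))
  do.call(rbind, rows)
}
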