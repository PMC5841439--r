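# Seeded synthetic-data generator with planted ground truth for every
# pipeline stage. Genes live in disjoint 1-kb windows on one synthetic
# chromosome; each gene carries two transcripts realizing exactly one
# alternative-splicing event of an assigned type. All randomness flows from
# config$seed through fixed per-stage offsets, so every emitted object is
# reproducible byte-for-byte under a fixed seed.

#' Simulation configuration
#'
#' Defaults mirror the desk-scale study conditions used throughout the
#' package: three samples per group, mean depth 100 with negative-binomial
#' spread, beta-binomial precision 10, a 10% planted-DAS fraction with
#' effect size |dPSI| = 0.3, base PSI uniform on (0.2, 0.8) and planted
#' proportions clipped to [0.02, 0.98].
#'
#' @param seed integer seed fixing every downstream draw.
#' @param events_per_type genes (= events) simulated per event type.
#' @param samples_per_group samples in each of case and control.
#' @param depth_mean,depth_size negative-binomial per-sample event depth
#'   (mean and size/dispersion).
#' @param psi_bounds uniform bounds of the base inclusion proportion.
#' @param planted_frac fraction of events planted as differential.
#' @param effect planted |dPSI| (sign randomized per event).
#' @param theta beta-binomial precision of the counts.
#' @param sub_rate per-base substitution rate between the two species.
#' @param conserved_frac,crossed_frac fractions of exon-skipping genes
#'   planted as straight-conserved / cross-matched (remainder independent).
#' @param n_sf number of splicing factors in the perturbation simulation.
#' @param regulon_frac fraction of events in each SF's regulon.
#' @param overlap fraction of the regulator's regulon echoed consistently in
#'   the disease dataset.
#' @param n_terms,genes_per_term,n_enriched_terms shape of the simulated
#'   term annotation.
#' @param neg_strand_frac fraction of genes placed on the minus strand.
#' @param read_length read length for read-level simulation.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed = 1, events_per_type = 5, samples_per_group = 3,
                       depth_mean = 100, depth_size = 10,
                       psi_bounds = c(0.2, 0.8), planted_frac = 0.1,
                       effect = 0.3, theta = 10, sub_rate = 0.1,
                       conserved_frac = 0.4, crossed_frac = 0.2,
                       n_sf = 3, regulon_frac = 0.3, overlap = 0.3,
                       n_terms = 20, genes_per_term = 15,
                       n_enriched_terms = 3, neg_strand_frac = 0.3,
                       read_length = 80) {
  cfg <- as.list(environment())
  stopifnot(psi_bounds[1] > 0, psi_bounds[2] < 1,
            planted_frac >= 0, planted_frac <= 1, theta > 0)
  class(cfg) <- "sim_config"
  cfg
}

sim_seed <- function(config, offset, stream = 0L) {
  set.seed((config$seed + 1000L * stream + offset) %% .Machine$integer.max)
}

WINDOW <- 1000L

# per-type gene templates: transcript exon chains plus the hand-specified
# truth event (inclusion/exclusion designation follows the event
# definitions, written down independently of enumerate_events)
gene_template <- function(type) {
  iv <- function(s, e) c(s, e)
  switch(type,
    ES = list(t1 = rbind(iv(50, 300), iv(400, 550), iv(650, 900)),
              t2 = rbind(iv(50, 300), iv(650, 900)),
              inc = rbind(iv(50, 300), iv(400, 550), iv(650, 900)),
              exc = rbind(iv(50, 300), iv(650, 900)),
              var = rbind(iv(400, 550))),
    A5SS = list(t1 = rbind(iv(50, 250), iv(500, 650)),
                t2 = rbind(iv(50, 180), iv(500, 650)),
                inc = rbind(iv(50, 250), iv(500, 650)),
                exc = rbind(iv(50, 180), iv(500, 650)),
                var = rbind(iv(180, 250))),
    A3SS = list(t1 = rbind(iv(50, 200), iv(420, 650)),
                t2 = rbind(iv(50, 200), iv(500, 650)),
                inc = rbind(iv(50, 200), iv(420, 650)),
                exc = rbind(iv(50, 200), iv(500, 650)),
                var = rbind(iv(420, 500))),
    ME = list(t1 = rbind(iv(50, 200), iv(300, 420), iv(600, 750)),
              t2 = rbind(iv(50, 200), iv(450, 520), iv(600, 750)),
              inc = rbind(iv(50, 200), iv(300, 420), iv(600, 750)),
              exc = rbind(iv(50, 200), iv(450, 520), iv(600, 750)),
              var = rbind(iv(300, 420), iv(450, 520))),
    IR = list(t1 = rbind(iv(50, 400)),
              t2 = rbind(iv(50, 200), iv(280, 400)),
              inc = rbind(iv(50, 400)),
              exc = rbind(iv(50, 200), iv(280, 400)),
              var = rbind(iv(200, 280))),
    AFE = list(t1 = rbind(iv(50, 150), iv(500, 650)),
               t2 = rbind(iv(250, 350), iv(500, 650)),
               inc = rbind(iv(250, 350), iv(500, 650)),
               exc = rbind(iv(50, 150), iv(500, 650)),
               var = rbind(iv(250, 350), iv(50, 150))),
    ALE = list(t1 = rbind(iv(50, 200), iv(400, 500)),
               t2 = rbind(iv(50, 200), iv(650, 750)),
               inc = rbind(iv(50, 200), iv(400, 500)),
               exc = rbind(iv(50, 200), iv(650, 750)),
               var = rbind(iv(400, 500), iv(650, 750))),
    stop("unknown event type: ", type))
}

mirror_mat <- function(m) {
  out <- cbind(WINDOW - m[, 2L], WINDOW - m[, 1L])
  out[order(out[, 1L]), , drop = FALSE]
}

shift_mat <- function(m, off) m + off

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate a one-species annotation with planted events
#'
#' Builds `events_per_type` genes per event type, each with two transcripts
#' realizing one event, on a single synthetic chromosome; a fraction of
#' genes is mirrored onto the minus strand (event types are preserved under
#' mirroring). The truth table records each planted event with its
#' hand-specified inclusion/exclusion chains.
#'
#' @param config a [sim_config()].
#' @param stream RNG stream offset (change to draw an independent species).
#' @param chrom chromosome name.
#' @param gene_prefix prefix for gene symbols.
#' @return list with `annotation` ([genome_annotation()]), `genome`
#'   (named [Biostrings::DNAStringSet]), and `truth` (a `splice_events`
#'   data.frame of the planted events).
#' @export
simulate_annotation <- function(config, stream = 0L, chrom = "chrA",
                                gene_prefix = "GA") {
  sim_seed(config, 0L, stream)
  types <- rep(EVENT_TYPES, each = config$events_per_type)
  n <- length(types)
  strands <- ifelse(runif(n) < config$neg_strand_frac, "-", "+")
  tx_rows <- list()
  truth <- list()
  for (i in seq_len(n)) {
    gid <- sprintf("%s%03d", gene_prefix, i)
    off <- (i - 1L) * WINDOW
    tpl <- gene_template(types[i])
    flip <- strands[i] == "-"
    adj <- function(m) shift_mat(if (flip) mirror_mat(m) else m, off)
    for (t in c("t1", "t2")) {
      ex <- adj(tpl[[t]])
      tx_rows[[length(tx_rows) + 1L]] <- data.frame(
        gene_id = gid, transcript_id = paste0(gid, ".", t), chrom = chrom,
        strand = strands[i], start = ex[, 1L], end = ex[, 2L],
        stringsAsFactors = FALSE)
    }
    var <- if (flip) {
      v <- shift_mat(cbind(WINDOW - tpl$var[, 2L], WINDOW - tpl$var[, 1L]),
                     off)
      v # variable regions keep role order (proximal/long first), not sorted
    } else shift_mat(tpl$var, off)
    truth[[i]] <- make_event(types[i], gid, chrom, strands[i],
                             adj(tpl$inc), adj(tpl$exc), var)
  }
  truth <- do.call(rbind, truth)
  class(truth) <- c("splice_events", "data.frame")
  genome <- Biostrings::DNAStringSet(setNames(random_dna(n * WINDOW), chrom))
  list(annotation = genome_annotation(do.call(rbind, tx_rows)),
       genome = genome, truth = truth)
}

#' Simulate a beta-binomial event count table
#'
#' Per event and sample, total depth is negative-binomial and the inclusion
#' count is beta-binomial with the group's inclusion proportion and the
#' configured precision. A planted fraction of events receives
#' `p_case = p_control + delta` with `delta = +/- effect` (random sign),
#' clipped to `[0.02, 0.98]`.
#'
#' @param config a [sim_config()].
#' @param events a `splice_events` data.frame (or anything with `event_id`).
#' @param planted optional data.frame (`event_id`, `delta`) overriding the
#'   random choice of planted events.
#' @param stream RNG stream offset.
#' @return list with `counts` (an `event_counts` data.frame, groups `case`
#'   and `control`) and `truth` (`event_id`, `p_control`, `p_case`,
#'   `delta`, `planted`).
#' @export
simulate_counts <- function(config, events, planted = NULL, stream = 0L) {
  sim_seed(config, 1L, stream)
  ids <- events$event_id
  m <- length(ids)
  p0 <- runif(m, config$psi_bounds[1], config$psi_bounds[2])
  delta <- numeric(m)
  if (is.null(planted)) {
    idx <- which(runif(m) < config$planted_frac)
    delta[idx] <- config$effect * sample(c(-1, 1), length(idx),
                                         replace = TRUE)
  } else {
    delta[match(planted$event_id, ids)] <- planted$delta
  }
  p1 <- clip(p0 + delta, 0.02, 0.98)
  nsg <- config$samples_per_group
  samples <- c(paste0("case_", seq_len(nsg)), paste0("ctrl_", seq_len(nsg)))
  groups <- rep(c("case", "control"), each = nsg)
  rows <- vector("list", m)
  for (i in seq_len(m)) {
    tot <- rnbinom(2L * nsg, mu = config$depth_mean, size = config$depth_size)
    p <- ifelse(groups == "case", p1[i], p0[i])
    k <- rbetabinom(2L * nsg, tot, p, config$theta)
    rows[[i]] <- data.frame(event_id = ids[i], sample_id = samples,
                            group = groups, n_inc = k, n_exc = tot - k,
                            stringsAsFactors = FALSE)
  }
  counts <- do.call(rbind, rows)
  class(counts) <- c("event_counts", "data.frame")
  list(counts = counts,
       truth = data.frame(event_id = ids, p_control = p0,
                          p_case = p1, delta = p1 - p0,
                          planted = delta != 0, stringsAsFactors = FALSE))
}

# map a spliced interval [u, u + len) on a chain (genomic order) to blocks
spliced_to_blocks <- function(chain, u, len) {
  widths <- chain[, 2L] - chain[, 1L]
  ends <- cumsum(widths)
  starts <- ends - widths
  lo <- u; hi <- u + len
  rows <- list()
  for (i in seq_len(nrow(chain))) {
    s <- max(lo, starts[i]); e <- min(hi, ends[i])
    if (e > s)
      rows[[length(rows) + 1L]] <-
        c(chain[i, 1L] + (s - starts[i]), chain[i, 1L] + (e - starts[i]))
  }
  do.call(rbind, rows)
}

#' Simulate reads from the isoforms of planted events
#'
#' Emits aligned-read blocks drawn uniformly along the spliced isoform
#' sequence of each event. Per read, the isoform is inclusion with
#' probability `psi` (or forced by `isoform`).
#'
#' @param config a [sim_config()].
#' @param events a `splice_events` data.frame.
#' @param n_reads reads per event.
#' @param psi inclusion probability per read (scalar or per-event vector).
#' @param isoform `"mixture"` (default), `"inclusion"` or `"exclusion"`.
#' @param sample_id sample label.
#' @param stream RNG stream offset.
#' @return an [aligned_reads()] object.
#' @export
simulate_event_reads <- function(config, events, n_reads = 200, psi = 0.5,
                                 isoform = c("mixture", "inclusion",
                                             "exclusion"),
                                 sample_id = "sim", stream = 0L) {
  isoform <- match.arg(isoform)
  sim_seed(config, 2L, stream)
  psi <- rep(psi, length.out = nrow(events))
  rl <- config$read_length
  chrom <- character(0); blocks <- list()
  for (i in seq_len(nrow(events))) {
    inc <- chain_mat(events$inclusion_chain[i])
    exc <- chain_mat(events$exclusion_chain[i])
    use_inc <- switch(isoform,
                      mixture = runif(n_reads) < psi[i],
                      inclusion = rep(TRUE, n_reads),
                      exclusion = rep(FALSE, n_reads))
    for (r in seq_len(n_reads)) {
      chain <- if (use_inc[r]) inc else exc
      L <- sum(chain[, 2L] - chain[, 1L])
      len <- min(rl, L)
      u <- sample.int(L - len + 1L, 1L) - 1L
      blocks[[length(blocks) + 1L]] <- spliced_to_blocks(chain, u, len)
      chrom <- c(chrom, events$chrom[i])
    }
  }
  aligned_reads(sample_id, chrom, blocks)
}

# substitute bases at a fixed per-base rate (always to a different base)
mutate_dna <- function(s, rate) {
  v <- strsplit(s, "")[[1L]]
  hit <- which(runif(length(v)) < rate)
  if (length(hit)) {
    for (i in hit) v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1L)
  }
  paste(v, collapse = "")
}

#' Simulate a homologous second species
#'
#' Clones each species-a gene into a species-b window. Exon-skipping genes
#' are planted as `conserved` (same geometry, sequence mutated at
#' `sub_rate`, same planted dPSI sign), `cross_matched` (the species-a
#' upstream and variable exons fused into one flanking exon, plus a novel
#' random variable exon, so the crossed isoform pairing wins), or
#' `independent` (same geometry, unrelated random sequence, independent
#' dPSI sign). Non-ES genes are conserved clones.
#'
#' @param config a [sim_config()].
#' @param sp_a result of [simulate_annotation()] for species a.
#' @param stream RNG stream offset.
#' @return list with `annotation`, `genome`, `truth` (planted species-b
#'   events), `homology` (a `homology_map`), and `classes` (data.frame
#'   `gene_a`, `gene_b`, `class`, `event_a`, `event_b`, `sign_a`,
#'   `sign_b`).
#' @export
simulate_two_species <- function(config, sp_a, stream = 0L) {
  sim_seed(config, 3L, stream)
  truth_a <- sp_a$truth
  ann_a <- sp_a$annotation
  seq_a <- as.character(sp_a$genome[[1L]])
  n <- nrow(truth_a)
  chrom <- "chrB"
  classes <- character(n)
  is_es <- truth_a$event_type == "ES"
  u <- runif(n)
  classes[is_es] <- ifelse(u[is_es] < config$conserved_frac, "conserved",
                    ifelse(u[is_es] < config$conserved_frac +
                             config$crossed_frac, "cross_matched",
                           "independent"))
  classes[!is_es] <- "conserved"
  sign_a <- sample(c(-1, 1), n, replace = TRUE)
  sign_b <- ifelse(classes == "independent",
                   sample(c(-1, 1), n, replace = TRUE), sign_a)
  tx_rows <- list(); truth_b <- list(); seq_b <- character(n)
  gene_b <- sprintf("GB%03d", seq_len(n))
  win_of <- function(i) substr(seq_a, (i - 1L) * WINDOW + 1L, i * WINDOW)
  for (i in seq_len(n)) {
    gid_a <- truth_a$gene_id[i]
    ga <- ann_a$genes[[gid_a]]
    off <- (i - 1L) * WINDOW
    if (classes[i] == "cross_matched") {
      # fused flank [50,450) carries the species-a U then V sequence; novel
      # variable exon [500,650); downstream [700,950) carries species-a D.
      # With these lengths the crossed isoform pairing wins the summed
      # identity deterministically and both crossed identities stay above
      # the 0.5 threshold at the default substitution rate.
      strand <- "+"
      t1 <- rbind(c(50L, 450L), c(500L, 650L), c(700L, 950L))
      t2 <- rbind(c(50L, 450L), c(700L, 950L))
      inc <- t1; exc <- t2; var <- rbind(c(500L, 650L))
      # species-a exon sequences in transcript orientation (the species-b
      # gene sits on the plus strand, so they are laid down forward)
      inc_a <- chain_mat(truth_a$inclusion_chain[i])
      exon_seq <- function(row) as.character(
        chain_seq(inc_a[row, , drop = FALSE], sp_a$genome[[1L]], ga$strand))
      ord <- if (ga$strand == "+") 1:3 else 3:1
      ua <- exon_seq(ord[1L]); va <- exon_seq(ord[2L])
      da <- exon_seq(ord[3L])
      w <- strsplit(random_dna(WINDOW), "")[[1L]]
      fused <- strsplit(mutate_dna(paste0(ua, va), config$sub_rate), "")[[1L]]
      w[51L:450L] <- fused
      w[701L:950L] <- strsplit(mutate_dna(da, config$sub_rate), "")[[1L]]
      seq_b[i] <- paste(w, collapse = "")
    } else {
      strand <- ga$strand
      t1 <- ga$transcripts[[1L]]$exons - off
      t2 <- ga$transcripts[[2L]]$exons - off
      inc <- chain_mat(truth_a$inclusion_chain[i]) - off
      exc <- chain_mat(truth_a$exclusion_chain[i]) - off
      var <- chain_mat(truth_a$variable_region[i]) - off
      seq_b[i] <- if (classes[i] == "independent") random_dna(WINDOW)
                  else mutate_dna(win_of(i), config$sub_rate)
    }
    for (tn in c("t1", "t2")) {
      ex <- (if (tn == "t1") t1 else t2) + off
      tx_rows[[length(tx_rows) + 1L]] <- data.frame(
        gene_id = gene_b[i], transcript_id = paste0(gene_b[i], ".", tn),
        chrom = chrom, strand = strand, start = ex[, 1L], end = ex[, 2L],
        stringsAsFactors = FALSE)
    }
    truth_b[[i]] <- make_event(truth_a$event_type[i], gene_b[i], chrom,
                               strand, inc + off, exc + off, var + off)
  }
  truth_b <- do.call(rbind, truth_b)
  class(truth_b) <- c("splice_events", "data.frame")
  homology <- homology_map(
    data.frame(group_id = seq_len(n), symbol = truth_a$gene_id),
    data.frame(group_id = seq_len(n), symbol = gene_b))
  genome_b <- Biostrings::DNAStringSet(
    setNames(paste(seq_b, collapse = ""), chrom))
  list(annotation = genome_annotation(do.call(rbind, tx_rows)),
       genome = genome_b, truth = truth_b, homology = homology,
       classes = data.frame(gene_a = truth_a$gene_id, gene_b = gene_b,
                            class = classes, event_a = truth_a$event_id,
                            event_b = truth_b$event_id, sign_a = sign_a,
                            sign_b = sign_b, stringsAsFactors = FALSE))
}

#' Simulate one perturbation/disease signature pair
#'
#' Signature-level generator for the connectivity-map workflow: over
#' `n_events` common events, a planted fraction (`overlap`) receives
#' identical non-zero symbols in both signatures; the remaining events draw
#' symbols independently (`+`/`-` each with probability `base_rate`). With
#' `overlap = 0` the two signatures are fully independent.
#'
#' @param n_events number of common events.
#' @param overlap planted agreement fraction.
#' @param base_rate probability of `+` (and of `-`) for unplanted events.
#' @param sf_gene label recorded on the perturbation signature.
#' @return list with `perturb` and `disease` `signature` objects.
#' @export
simulate_signature_pair <- function(n_events = 200, overlap = 0.3,
                                    base_rate = 0.2, sf_gene = "SF1") {
  ids <- sprintf("E%04d", seq_len(n_events))
  draw <- function(m) sample(c("+", "-", "0"), m, replace = TRUE,
                             prob = c(base_rate, base_rate,
                                      1 - 2 * base_rate))
  sp <- draw(n_events); sd <- draw(n_events)
  k <- round(overlap * n_events)
  if (k > 0) {
    idx <- sample.int(n_events, k)
    sym <- sample(c("+", "-"), k, replace = TRUE)
    sp[idx] <- sym; sd[idx] <- sym
  }
  list(perturb = new_signature(ids, sp, sf_gene = sf_gene),
       disease = new_signature(ids, sd))
}

#' Simulate count-level splicing-factor perturbation studies
#'
#' The first SF is the planted regulator: its regulon events shift in its
#' perturbation dataset (direction-aware: knockdown/knockout reverses the
#' overexpression effect) and a fraction (`overlap`) of the regulon shifts
#' consistently in the disease dataset, oriented by the SF's planted
#' expression change. Remaining SFs are non-regulators with their own
#' regulons but no disease echo. Each SF also receives a gene-expression
#' matrix in the disease comparison with its own gene scaled according to
#' the planted expression direction.
#'
#' @param config a [sim_config()].
#' @param events a `splice_events` data.frame.
#' @param stream RNG stream offset.
#' @return list with `meta` (data.frame `dataset_id`, `sf_gene`,
#'   `direction`, `expr_dir`), `perturb_counts` (named list of
#'   `event_counts`), `disease_counts` (one `event_counts`), `expression`
#'   (gene-by-sample matrix for the disease comparison, case columns
#'   prefixed `case_`), and `truth` (regulator flag and per-SF regulon with
#'   signs).
#' @export
simulate_sf_perturbations <- function(config, events, stream = 0L) {
  sim_seed(config, 4L, stream)
  ids <- events$event_id
  m <- length(ids)
  n_sf <- config$n_sf
  sf_genes <- sprintf("SF%d", seq_len(n_sf))
  directions <- sample(c("OE", "KD", "KO"), n_sf, replace = TRUE)
  expr_dirs <- sample(c("up", "down"), n_sf, replace = TRUE)
  regulons <- lapply(seq_len(n_sf), function(s) {
    k <- max(1L, round(config$regulon_frac * m))
    idx <- sample.int(m, k)
    data.frame(event_id = ids[idx],
               sign = sample(c(-1, 1), k, replace = TRUE),
               stringsAsFactors = FALSE)
  })
  perturb_counts <- list()
  for (s in seq_len(n_sf)) {
    dirfac <- if (directions[s] == "OE") 1 else -1
    planted <- data.frame(event_id = regulons[[s]]$event_id,
                          delta = config$effect * regulons[[s]]$sign * dirfac)
    perturb_counts[[sf_genes[s]]] <-
      simulate_counts(config, events, planted = planted,
                      stream = stream + 10L + s)$counts
  }
  # disease dataset: echo of the regulator's regulon, oriented by its
  # planted expression direction
  reg <- regulons[[1L]]
  k <- round(config$overlap * nrow(reg))
  echo <- reg[seq_len(k), , drop = FALSE]
  exprfac <- if (expr_dirs[1L] == "up") 1 else -1
  disease_planted <- if (k > 0)
    data.frame(event_id = echo$event_id,
               delta = config$effect * echo$sign * exprfac)
  else NULL
  disease_counts <- simulate_counts(config, events,
                                    planted = disease_planted,
                                    stream = stream + 10L + n_sf + 1L)$counts
  # disease expression matrix: SF genes + background, NB counts
  sim_seed(config, 5L, stream)
  nsg <- config$samples_per_group
  samples <- c(paste0("case_", seq_len(nsg)), paste0("ctrl_", seq_len(nsg)))
  genes <- c(sf_genes, sprintf("BG%03d", seq_len(50L)))
  base <- matrix(rnbinom(length(genes) * length(samples), mu = 200,
                         size = 20),
                 nrow = length(genes),
                 dimnames = list(genes, samples))
  base[base == 0L] <- 1L
  for (s in seq_len(n_sf)) {
    fold <- if (expr_dirs[s] == "up") 3 else 1 / 3
    base[sf_genes[s], seq_len(nsg)] <-
      pmax(1L, as.integer(round(base[sf_genes[s], seq_len(nsg)] * fold)))
  }
  list(meta = data.frame(dataset_id = paste0("DS_", sf_genes),
                         sf_gene = sf_genes, direction = directions,
                         expr_dir = expr_dirs, stringsAsFactors = FALSE),
       perturb_counts = perturb_counts, disease_counts = disease_counts,
       expression = base,
       truth = list(regulator = sf_genes[1L], regulons =
                      setNames(regulons, sf_genes)))
}

#' Simulate a term annotation with planted enriched terms
#'
#' @param config a [sim_config()].
#' @param foreground,background gene symbol vectors.
#' @param stream RNG stream offset.
#' @return list with `terms` (a `term_annotation` data.frame) and
#'   `enriched` (term ids planted as enriched: half of their genes drawn
#'   from the foreground).
#' @export
simulate_terms <- function(config, foreground, background, stream = 0L) {
  sim_seed(config, 6L, stream)
  rows <- list()
  enriched <- sprintf("T%03d", seq_len(config$n_enriched_terms))
  for (t in seq_len(config$n_terms)) {
    tid <- sprintf("T%03d", t)
    gpt <- min(config$genes_per_term, length(background))
    if (tid %in% enriched && length(foreground)) {
      k <- min(ceiling(gpt / 2), length(foreground))
      pool <- setdiff(background, foreground)
      genes <- c(sample(foreground, k),
                 if (length(pool)) sample(pool, min(gpt - k, length(pool))))
    } else {
      genes <- sample(background, gpt)
    }
    rows[[t]] <- data.frame(term_id = tid, term_name = paste0("term ", t),
                            gene = unique(genes), stringsAsFactors = FALSE)
  }
  terms <- do.call(rbind, rows)
  class(terms) <- c("term_annotation", "data.frame")
  list(terms = terms, enriched = enriched)
}
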