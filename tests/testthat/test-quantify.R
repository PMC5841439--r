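test_that("junction matching is exact and body counting requires containment", {
  ann <- cassette_annotation()
  rds <- aligned_reads("s1", rep("chr1", 4L), list(
    rbind(c(150L, 200L), c(300L, 350L)),  # exact U-V junction
    rbind(c(150L, 199L), c(300L, 350L)),  # one base short: no junction
    rbind(c(320L, 380L)),                 # inside V: body count
    rbind(c(380L, 420L))))                # straddles V end: no body count
  fc <- count_features(rds, ann)
  # only the boundary-exact read supports the annotated junction; the
  # off-by-one read records its own (unused) junction key
  expect_equal(unname(fc$s1$junction["chr1:200-300"]), 1L)
  expect_equal(unname(fc$s1$junction["chr1:199-300"]), 1L)
  # contained blocks count (including the junction read's block inside V);
  # the straddling block does not
  expect_equal(unname(fc$s1$body["chr1:300-400"]), 3L)
})

test_that("per-type assignment rules produce the documented sums", {
  ann <- cassette_annotation()
  ev <- enumerate_events(ann)
  # ES with feature counts J(U->V)=6, J(V->D)=4, body(V)=10, J(U->D)=5
  # gives (n_inc, n_exc) = (20, 5)
  fc <- structure(list(s1 = list(
    junction = c("chr1:200-300" = 6L, "chr1:400-500" = 4L,
                 "chr1:200-500" = 5L),
    body = c("chr1:300-400" = 10L),
    intron = integer(0))), class = "feature_counts")
  ec <- assign_event_counts(ev, fc, groups = c(s1 = "case"))
  expect_equal(ec$n_inc, 20L)
  expect_equal(ec$n_exc, 5L)
  # IR with no intron support and 12 skip reads gives (0, 12)
  ann2 <- genome_annotation(data.frame(
    gene_id = "g", transcript_id = rep(c("t1", "t2"), c(1L, 2L)),
    chrom = "c", strand = "+",
    start = c(0L, 0L, 300L), end = c(400L, 100L, 400L)))
  ev2 <- enumerate_events(ann2)
  fc2 <- structure(list(s1 = list(
    junction = c("c:100-300" = 12L), body = integer(0),
    intron = integer(0))), class = "feature_counts")
  ec2 <- assign_event_counts(ev2, fc2, groups = c(s1 = "case"))
  expect_equal(ec2$n_inc, 0L)
  expect_equal(ec2$n_exc, 12L)
})

test_that("intron-retention counts body, boundary-spanning and skip reads", {
  ann <- genome_annotation(data.frame(
    gene_id = "g", transcript_id = rep(c("t1", "t2"), c(1L, 2L)),
    chrom = "c", strand = "+",
    start = c(0L, 0L, 300L), end = c(400L, 100L, 400L)))
  ev <- enumerate_events(ann)
  expect_equal(ev$event_type, "IR")
  blocks <- c(
    replicate(3L, rbind(c(150L, 250L)), simplify = FALSE),   # within intron
    replicate(2L, rbind(c(80L, 160L)), simplify = FALSE),    # spans left boundary
    replicate(12L, rbind(c(60L, 100L), c(300L, 340L)), simplify = FALSE)) # skip
  rds <- aligned_reads("s1", rep("c", 17L), blocks)
  fc <- count_features(rds, ann, events = ev)
  ec <- assign_event_counts(ev, fc, groups = c(s1 = "x"))
  expect_equal(ec$n_inc, 5L)
  expect_equal(ec$n_exc, 12L)
})

test_that("reads confined to one isoform never support the other", {
  cfg <- sim_config(seed = 11, events_per_type = 2)
  sp <- simulate_annotation(cfg)
  ev <- enumerate_events(sp$annotation)
  rds <- simulate_event_reads(cfg, ev, n_reads = 60, isoform = "inclusion",
                              sample_id = "s1")
  fc <- count_features(rds, sp$annotation, events = ev)
  ec <- assign_event_counts(ev, fc, groups = c(s1 = "case"))
  expect_true(all(ec$n_exc == 0L))
  expect_gt(sum(ec$n_inc), 0L)
  rde <- simulate_event_reads(cfg, ev, n_reads = 60, isoform = "exclusion",
                              sample_id = "s2", stream = 5L)
  fce <- count_features(rde, sp$annotation, events = ev)
  ece <- assign_event_counts(ev, fce, groups = c(s2 = "case"))
  expect_true(all(ece$n_inc == 0L))
  expect_gt(sum(ece$n_exc), 0L)
})

test_that("counting is additive over read batches", {
  cfg <- sim_config(seed = 12, events_per_type = 1)
  sp <- simulate_annotation(cfg)
  ev <- enumerate_events(sp$annotation)
  rds <- simulate_event_reads(cfg, ev, n_reads = 100, psi = 0.5,
                              sample_id = "s")
  half <- length(rds$blocks) %/% 2L
  b1 <- aligned_reads("s", rds$chrom[1:half], rds$blocks[1:half])
  b2 <- aligned_reads("s", rds$chrom[(half + 1):length(rds$chrom)],
                      rds$blocks[(half + 1):length(rds$blocks)])
  g <- c(s = "x")
  full <- assign_event_counts(ev, count_features(rds, sp$annotation, ev), g)
  p1 <- assign_event_counts(ev, count_features(b1, sp$annotation, ev), g)
  p2 <- assign_event_counts(ev, count_features(b2, sp$annotation, ev), g)
  expect_equal(full$n_inc, p1$n_inc + p2$n_inc)
  expect_equal(full$n_exc, p1$n_exc + p2$n_exc)
})

test_that("mixture reads recover the expected count-level inclusion ratio", {
  # the informative-position fractions of the two isoforms differ, so the
  # expected count ratio is derived by enumerating read placements
  cfg <- sim_config(seed = 13, events_per_type = 1, read_length = 80)
  sp <- simulate_annotation(cfg)
  ev <- enumerate_events(sp$annotation)
  es <- ev[ev$event_type == "ES", ]
  psi <- 0.7
  n_reads <- 1000L
  rds <- simulate_event_reads(cfg, es, n_reads = n_reads, psi = psi,
                              sample_id = "s")
  fc <- count_features(rds, sp$annotation, events = ev)
  ec <- assign_event_counts(es, fc, groups = c(s = "x"))
  # enumeration oracle: expected feature counts per read of each isoform
  weight <- function(chain_str, count_fun) {
    chain <- chain_mat(chain_str)
    L <- sum(chain[, 2L] - chain[, 1L])
    tot <- 0
    for (u in 0:(L - 80L))
      tot <- tot + count_fun(spliceDAS:::spliced_to_blocks(chain, u, 80L))
    tot / (L - 80L + 1L)
  }
  inc <- chain_mat(es$inclusion_chain)
  v <- inc[2L, ]
  count_inc <- function(b) {
    jk <- if (nrow(b) > 1L) paste(b[-nrow(b), 2L], b[-1L, 1L]) else character(0)
    sum(jk %in% c(paste(inc[1L, 2L], inc[2L, 1L]),
                  paste(inc[2L, 2L], inc[3L, 1L]))) +
      any(b[, 1L] >= v[1L] & b[, 2L] <= v[2L])
  }
  exc <- chain_mat(es$exclusion_chain)
  count_exc <- function(b) {
    jk <- if (nrow(b) > 1L) paste(b[-nrow(b), 2L], b[-1L, 1L]) else character(0)
    sum(jk %in% paste(exc[1L, 2L], exc[2L, 1L]))
  }
  w_inc <- weight(es$inclusion_chain, count_inc)
  w_exc <- weight(es$exclusion_chain, count_exc)
  r_expected <- psi * w_inc / (psi * w_inc + (1 - psi) * w_exc)
  r_observed <- ec$n_inc / (ec$n_inc + ec$n_exc)
  # 99% binomial-style tolerance at this depth
  expect_lt(abs(r_observed - r_expected),
            2.58 * sqrt(r_expected * (1 - r_expected) / n_reads) + 0.02)
})

test_that("BED12 round trip preserves read blocks", {
  cfg <- sim_config(seed = 14, events_per_type = 1)
  sp <- simulate_annotation(cfg)
  ev <- enumerate_events(sp$annotation)
  rds <- simulate_event_reads(cfg, ev, n_reads = 20, sample_id = "s1")
  f <- withr::local_tempfile(fileext = ".bed")
  write_bed12(rds, f)
  rds2 <- read_bed12(f, "s1")
  expect_equal(rds2$chrom, rds$chrom)
  expect_equal(lapply(rds2$blocks, unname), lapply(rds$blocks, unname))
})

test_that("zero reads yield an all-zero table and unknown chromosomes warn", {
  ann <- cassette_annotation()
  ev <- enumerate_events(ann)
  none <- aligned_reads("s1", character(0), list())
  fc <- count_features(none, ann, events = ev)
  ec <- assign_event_counts(ev, fc, groups = c(s1 = "x"))
  expect_true(all(ec$n_inc == 0L & ec$n_exc == 0L))
  stray <- aligned_reads("s1", "chrZ", list(rbind(c(0L, 50L))))
  expect_warning(count_features(stray, ann), "unknown")
})
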