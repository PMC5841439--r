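# Shared fixtures built in code: toy annotations, oracle implementations.

# simple one-gene cassette annotation: transcripts U-V-D and U-D
cassette_annotation <- function(strand = "+") {
  genome_annotation(data.frame(
    gene_id = "g1",
    transcript_id = rep(c("t1", "t2"), c(3L, 2L)),
    chrom = "chr1", strand = strand,
    start = c(100L, 300L, 500L, 100L, 500L),
    end = c(200L, 400L, 600L, 200L, 600L),
    stringsAsFactors = FALSE))
}

# four-transcript toy gene containing exactly one event of each of the
# seven types (seven two-variant modules between constitutive anchors);
# expected events are hand-enumerated below
seven_type_gene <- function() {
  # module variants per transcript (v1 or v2 per column)
  # AFE: first exon A=[0,100) (v1) or B=[200,300) (v2); anchor C=[400,500)
  # ES:  cassette V=[600,700) present (v1) or absent (v2); anchor D=[800,900)
  # A5SS: P=[1000,1150) long (v1) or [1000,1100) short (v2); anchor Q=[1300,1400)
  # A3SS: S=[1650,1800) long (v1) or [1700,1800) short (v2); anchor R=[1500,1600)
  # IR:  retained [2100,2300) (v1) or spliced F=[2100,2150),G=[2250,2300) (v2)
  # ME:  M1=[2600,2720) (v1) or M2=[2750,2850) (v2); anchors U=[2400,2500), W=[2900,3000)
  # ALE: last exon Z1=[3100,3200) (v1) or Z2=[3300,3400) (v2)
  mods <- list(
    AFE = list(v1 = rbind(c(0L, 100L)), v2 = rbind(c(200L, 300L))),
    C = rbind(c(400L, 500L)),
    ES = list(v1 = rbind(c(600L, 700L)), v2 = NULL),
    D = rbind(c(800L, 900L)),
    A5SS = list(v1 = rbind(c(1000L, 1150L)), v2 = rbind(c(1000L, 1100L))),
    Q = rbind(c(1300L, 1400L)),
    R = rbind(c(1500L, 1600L)),
    A3SS = list(v1 = rbind(c(1650L, 1800L)), v2 = rbind(c(1700L, 1800L))),
    T = rbind(c(1900L, 2000L)),
    IR = list(v1 = rbind(c(2100L, 2300L)),
              v2 = rbind(c(2100L, 2150L), c(2250L, 2300L))),
    U = rbind(c(2400L, 2500L)),
    ME = list(v1 = rbind(c(2600L, 2720L)), v2 = rbind(c(2750L, 2850L))),
    W = rbind(c(2900L, 3000L)),
    ALE = list(v1 = rbind(c(3100L, 3200L)), v2 = rbind(c(3300L, 3400L))))
  pick <- list(
    t1 = c(AFE = "v1", ES = "v1", A5SS = "v1", A3SS = "v2", IR = "v2",
           ME = "v1", ALE = "v1"),
    t2 = c(AFE = "v2", ES = "v2", A5SS = "v2", A3SS = "v1", IR = "v1",
           ME = "v2", ALE = "v2"),
    t3 = c(AFE = "v1", ES = "v2", A5SS = "v2", A3SS = "v2", IR = "v2",
           ME = "v2", ALE = "v1"),
    t4 = c(AFE = "v2", ES = "v1", A5SS = "v1", A3SS = "v1", IR = "v1",
           ME = "v1", ALE = "v2"))
  rows <- list()
  for (tid in names(pick)) {
    ex <- list()
    for (mn in names(mods)) {
      m <- mods[[mn]]
      ex[[mn]] <- if (is.list(m)) m[[pick[[tid]][mn]]] else m
    }
    ex <- do.call(rbind, ex)
    ex <- ex[order(ex[, 1L]), , drop = FALSE]
    rows[[tid]] <- data.frame(gene_id = "g7", transcript_id = tid,
                              chrom = "chr7", strand = "+",
                              start = ex[, 1L], end = ex[, 2L],
                              stringsAsFactors = FALSE)
  }
  genome_annotation(do.call(rbind, rows))
}

# hand enumeration of the seven events of seven_type_gene()
seven_type_expected <- function() {
  ch <- function(...) {
    m <- rbind(...)
    paste(paste0(m[, 1], "-", m[, 2]), collapse = ",")
  }
  data.frame(
    event_type = c("AFE", "ES", "A5SS", "A3SS", "IR", "ME", "ALE"),
    inclusion_chain = c(
      ch(c(200, 300), c(400, 500)),
      ch(c(400, 500), c(600, 700), c(800, 900)),
      ch(c(1000, 1150), c(1300, 1400)),
      ch(c(1500, 1600), c(1650, 1800)),
      ch(c(2100, 2300)),
      ch(c(2400, 2500), c(2600, 2720), c(2900, 3000)),
      ch(c(2900, 3000), c(3100, 3200))),
    exclusion_chain = c(
      ch(c(0, 100), c(400, 500)),
      ch(c(400, 500), c(800, 900)),
      ch(c(1000, 1100), c(1300, 1400)),
      ch(c(1500, 1600), c(1700, 1800)),
      ch(c(2100, 2150), c(2250, 2300)),
      ch(c(2400, 2500), c(2750, 2850), c(2900, 3000)),
      ch(c(2900, 3000), c(3300, 3400))),
    stringsAsFactors = FALSE)
}

# one-sided hypergeometric summation oracle for the central Fisher test on
# [[a, b], [c, d]] (enrichment direction: greater)
fisher_oracle <- function(a, b, c_, d) {
  m1 <- a + b; k <- a + c_; N <- a + b + c_ + d
  xs <- max(0L, k - (N - m1)):min(k, m1)
  w <- dhyper(xs, m1, N - m1, k)
  sum(w[xs >= a])
}

# noncentral hypergeometric upper-tail oracle at odds ratio `psi`
ncfisher_oracle <- function(a, b, c_, d, psi) {
  m1 <- a + b; k <- a + c_; N <- a + b + c_ + d
  xs <- max(0L, k - (N - m1)):min(k, m1)
  lw <- lchoose(m1, xs) + lchoose(N - m1, k - xs) + xs * log(psi)
  w <- exp(lw - max(lw))
  sum(w[xs >= a]) / sum(w)
}

# dense two-stage grid-search oracle for the beta-binomial log-likelihood
grid_oracle_loglik <- function(k, n, groups = NULL) {
  if (is.null(groups)) groups <- rep("all", length(k))
  gf <- factor(groups); gidx <- as.integer(gf); G <- nlevels(gf)
  eval_ll <- function(p, theta) {
    betabin_loglik(k, n, p[gidx], theta)
  }
  best <- -Inf; best_par <- NULL
  scan <- function(ps_list, ths) {
    grid <- as.matrix(expand.grid(ps_list))
    for (th in ths) for (r in seq_len(nrow(grid))) {
      ll <- eval_ll(grid[r, ], th)
      if (ll > best) { best <<- ll; best_par <<- c(grid[r, ], th) }
    }
  }
  # coarse pass over the model's admissible box, then shrinking passes
  # centered on the running optimum
  scan(rep(list(seq(0.001, 0.999, length.out = 50)), G),
       exp(seq(-5, 10, length.out = 60)))
  wp <- 0.05; wt <- 0.5
  for (rep in 1:5) {
    ps_loc <- lapply(seq_len(G), function(g)
      seq(max(1e-4, best_par[g] - wp), min(1 - 1e-4, best_par[g] + wp),
          length.out = 21))
    lt <- log(best_par[G + 1L])
    th_loc <- exp(seq(max(-5, lt - wt), min(10, lt + wt), length.out = 21))
    scan(ps_loc, th_loc)
    wp <- wp / 8; wt <- wt / 8
  }
  list(logLik = best, par = best_par)
}
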