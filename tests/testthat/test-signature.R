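test_that("size factors follow the median-of-ratios contract", {
  m <- matrix(c(2, 2, 8, 8), nrow = 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_equal(unname(size_factors(m)), c(0.5, 2.0))
  # identical samples: all factors 1
  m2 <- matrix(rep(c(3, 7, 11), 3L), nrow = 3,
               dimnames = list(paste0("g", 1:3), paste0("s", 1:3)))
  expect_equal(unname(size_factors(m2)), rep(1, 3))
  # homogeneity: scaling one sample scales its factor relative to the rest
  # (size factors are defined up to a common normalization)
  m3 <- m2; m3[, 2] <- m3[, 2] * 4
  f2 <- size_factors(m2); f3 <- size_factors(m3)
  expect_equal(unname(f3[2] / f3[1]), unname(4 * f2[2] / f2[1]))
  expect_error(size_factors(matrix(c(0, 1, 1, 0), 2)), "non-zero")
})

test_that("size factors agree with the DESeq2 reference implementation", {
  set.seed(17)
  m <- matrix(rnbinom(300, mu = 50, size = 5) + 1L, nrow = 50,
              dimnames = list(paste0("g", 1:50), paste0("s", 1:6)))
  expect_equal(unname(size_factors(m)),
               unname(DESeq2::estimateSizeFactorsForMatrix(m)),
               tolerance = 1e-8)
})

test_that("SF direction reflects normalized fold change", {
  # housekeeping genes identical across samples, so all size factors but
  # the SF's own signal cancel out
  m <- matrix(c(40, 44, 10, 12,
                100, 100, 100, 100,
                50, 50, 50, 50), nrow = 3, byrow = TRUE,
              dimnames = list(c("SF1", "h1", "h2"),
                              c("case_1", "case_2", "ctrl_1", "ctrl_2")))
  expect_equal(sf_direction(m, "SF1", 1:2, 3:4), "up")
  m["SF1", ] <- c(10, 12, 40, 44)
  expect_equal(sf_direction(m, "SF1", 1:2, 3:4), "down")
  m["SF1", ] <- c(50, 50, 50, 50)
  expect_equal(sf_direction(m, "SF1", 1:2, 3:4), "undetermined")
  expect_error(sf_direction(m, "nope", 1:2, 3:4), "not found")
})

test_that("a planted knockdown is detected as down", {
  hits <- 0L
  set.seed(23)
  for (b in 1:100) {
    m <- matrix(rnbinom(40 * 6, mu = 100, size = 10) + 1L, nrow = 40,
                dimnames = list(c("SF1", paste0("g", 2:40)),
                                c(paste0("case_", 1:3), paste0("ctrl_", 1:3))))
    m["SF1", 1:3] <- pmax(1L, as.integer(round(m["SF1", 1:3] / 3)))
    hits <- hits + (sf_direction(m, "SF1", 1:3, 4:6) == "down")
  }
  expect_gte(hits, 99L)
})

test_that("perturbation signatures orient by perturbation direction", {
  das <- structure(data.frame(
    event_id = c("e1", "e2", "e3", "e4"),
    delta_psi = c(0.2, -0.2, 0.2, 0.02),
    q = c(0.01, 0.01, 0.2, 0.01)), class = c("das", "data.frame"))
  oe <- perturbation_signature(das, "OE")
  expect_equal(oe$symbol, c("+", "-", "0", "0"))
  ko <- perturbation_signature(das, "KO")
  expect_equal(ko$symbol, c("-", "+", "0", "0"))
  expect_error(perturbation_signature(das, "XX"), "direction")
})

test_that("disease signatures orient by SF expression direction", {
  das <- structure(data.frame(
    event_id = c("e1", "e2", "e3"),
    delta_psi = c(0.2, -0.2, 0.0),
    q = c(0.01, 0.01, 0.5)), class = c("das", "data.frame"))
  up <- disease_signature(das, "up")
  expect_equal(up$symbol, c("+", "-", "0"))
  down <- disease_signature(das, "down")
  expect_equal(down$symbol, c("-", "+", "0"))
  expect_message(out <- disease_signature(das, "undetermined"), "skipping")
  expect_null(out)
})

test_that("identical signatures give the enumerated hypergeometric p", {
  ids <- sprintf("e%02d", 1:20)
  sym <- c(rep("+", 5), rep("-", 5), rep("0", 10))
  s1 <- spliceDAS:::new_signature(ids, sym)
  s2 <- spliceDAS:::new_signature(ids, sym)
  cm <- compare_signatures(s1, s2)
  expect_equal(unname(cm$p_pp), 1 / choose(20, 5), tolerance = 1e-10)
  expect_equal(unname(cm$p_mm), 1 / choose(20, 5), tolerance = 1e-10)
  expect_true(cm$candidate)
  expect_equal(sum(cm$table), 20)
  # all-zero disease signature: degenerate tables, no candidate
  s0 <- spliceDAS:::new_signature(ids, rep("0", 20))
  cm0 <- compare_signatures(s1, s0)
  expect_equal(unname(c(cm0$p_pp, cm0$p_mm)), c(1, 1))
  expect_false(cm0$candidate)
})

test_that("swapping the signatures transposes the table, keeping both p-values", {
  set.seed(3)
  pr <- simulate_signature_pair(100, overlap = 0.2)
  c1 <- compare_signatures(pr$perturb, pr$disease)
  c2 <- compare_signatures(pr$disease, pr$perturb)
  expect_equal(unclass(c2$table), t(unclass(c1$table)),
               ignore_attr = TRUE)
  expect_equal(c1$p_pp, c2$p_pp)
  expect_equal(c1$p_mm, c2$p_mm)
})

test_that("collapsed 2x2 tables conserve the 3x3 total", {
  set.seed(4)
  pr <- simulate_signature_pair(150, overlap = 0.3)
  cm <- compare_signatures(pr$perturb, pr$disease)
  expect_equal(sum(cm$table), cm$n_common)
  expect_equal(cm$n_common, 150L)
})

test_that("regulator attribution requires matching non-zero symbols", {
  ids <- c("e1", "e2", "e3", "e4")
  sp <- list(SF1 = spliceDAS:::new_signature(ids, c("+", "+", "-", "0"),
                                             sf_gene = "SF1"))
  sd <- spliceDAS:::new_signature(ids, c("+", "-", "-", "+"))
  out <- conserved_event_regulators(ids, sp, sd)
  expect_equal(out$SF1, c("e1", "e3"))
  # zero-signature events never attributed
  out2 <- conserved_event_regulators("e4", sp, sd)
  expect_length(out2, 0L)
})

test_that("the count-level SF workflow recovers the planted regulator", {
  cfg <- sim_config(seed = 55, events_per_type = 6, theta = 50,
                    depth_mean = 200, effect = 0.3, regulon_frac = 0.4,
                    overlap = 1.0, n_sf = 2)
  sp <- simulate_annotation(cfg)
  ev <- enumerate_events(sp$annotation)
  sf <- simulate_sf_perturbations(cfg, ev)
  res <- list()
  for (s in seq_len(nrow(sf$meta))) {
    sfg <- sf$meta$sf_gene[s]
    das_p <- das_test(sf$perturb_counts[[sfg]], "case", "control")
    sig_p <- perturbation_signature(das_p, sf$meta$direction[s],
                                    sf_gene = sfg)
    dirn <- sf_direction(sf$expression, sfg,
                         grep("^case_", colnames(sf$expression)),
                         grep("^ctrl_", colnames(sf$expression)))
    expect_equal(dirn, sf$meta$expr_dir[s])
    das_d <- das_test(sf$disease_counts, "case", "control")
    sig_d <- disease_signature(das_d, dirn)
    res[[sfg]] <- compare_signatures(sig_p, sig_d)
  }
  expect_true(res[[sf$truth$regulator]]$candidate)
})
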