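# Splicing-signature connectivity mapping: orient per-event splicing calls
# into +/-/0 signatures for splicing-factor (SF) perturbation datasets and
# for disease datasets, compare signatures via a 3x3 table collapsed into
# 2x2 Fisher tests of ++ and -- enrichment, and attribute conserved events
# to candidate SFs.

#' Median-of-ratios size factors
#'
#' Per-sample scaling factors: the median over genes with non-zero counts in
#' every sample of the ratio between the sample's count and the gene's
#' geometric mean across samples.
#'
#' @param mat gene-by-sample matrix of non-negative integer counts.
#' @return named numeric vector of positive factors, one per sample.
#' @export
size_factors <- function(mat) {
  mat <- as.matrix(mat)
  if (any(mat < 0)) stop("counts must be non-negative")
  allpos <- rowSums(mat == 0) == 0L
  if (!any(allpos))
    stop("no gene has non-zero counts in all samples; filter the matrix")
  sub <- mat[allpos, , drop = FALSE]
  lgeo <- rowMeans(log(sub))
  # median taken on the log-ratio scale (geometric interpolation at ties),
  # matching the reference median-of-ratios implementation
  exp(apply(log(sub) - lgeo, 2L, median))
}

#' Expression direction of a splicing factor
#'
#' Normalizes the count matrix by [size_factors()] and compares the mean
#' normalized expression of the SF gene between groups: `"up"` if the fold
#' change exceeds 1, `"down"` if below 1, `"undetermined"` at exactly 1 or
#' when the control mean is 0.
#'
#' @param mat gene-by-sample count matrix (rownames = gene symbols).
#' @param sf_gene gene symbol of the splicing factor.
#' @param case_samples,control_samples column names (or indices) of the two
#'   groups.
#' @return `"up"`, `"down"` or `"undetermined"`.
#' @export
sf_direction <- function(mat, sf_gene, case_samples, control_samples) {
  mat <- as.matrix(mat)
  if (!sf_gene %in% rownames(mat)) stop("gene not found: ", sf_gene)
  sf <- size_factors(mat)
  norm <- sweep(mat, 2L, sf, "/")
  mc <- mean(norm[sf_gene, case_samples])
  m0 <- mean(norm[sf_gene, control_samples])
  if (m0 == 0 || mc == m0) return("undetermined")
  if (mc > m0) "up" else "down"
}

# classify per-event splicing change at the signature thresholds
event_change <- function(das, dpsi_threshold = 0.05, q_threshold = 0.05) {
  ch <- rep("0", nrow(das))
  up <- !is.na(das$q) & das$q < q_threshold & das$delta_psi > dpsi_threshold
  dn <- !is.na(das$q) & das$q < q_threshold & das$delta_psi < -dpsi_threshold
  ch[up] <- "up"; ch[dn] <- "down"
  ch
}

new_signature <- function(event_id, symbol, dataset = NA_character_,
                          sf_gene = NA_character_) {
  stopifnot(all(symbol %in% c("+", "-", "0")))
  structure(data.frame(event_id = event_id, symbol = symbol,
                       stringsAsFactors = FALSE),
            class = c("signature", "data.frame"),
            dataset = dataset, sf_gene = sf_gene)
}

#' Splicing signature of an SF-perturbation dataset
#'
#' An event is positively regulated (`+`) when its variable-exon inclusion
#' rises upon SF overexpression or falls upon knockdown/knockout; negatively
#' regulated (`-`) in the mirrored cases; `0` otherwise. Splicing changes
#' are called at `dPSI > 0.05` / `dPSI < -0.05` with `q < 0.05`.
#'
#' @param das a `das` result for the perturbation dataset (case = perturbed).
#' @param direction perturbation direction: `"OE"`, `"KD"` or `"KO"`.
#' @param dataset optional dataset id recorded on the signature.
#' @param sf_gene optional SF gene symbol recorded on the signature.
#' @param dpsi_threshold,q_threshold change-call thresholds.
#' @return a `signature` data.frame (`event_id`, `symbol`).
#' @export
perturbation_signature <- function(das, direction, dataset = NA_character_,
                                   sf_gene = NA_character_,
                                   dpsi_threshold = 0.05,
                                   q_threshold = 0.05) {
  if (!direction %in% c("OE", "KD", "KO"))
    stop("unknown perturbation direction: ", direction)
  ch <- event_change(das, dpsi_threshold, q_threshold)
  sym <- rep("0", length(ch))
  if (direction == "OE") {
    sym[ch == "up"] <- "+"; sym[ch == "down"] <- "-"
  } else {
    sym[ch == "down"] <- "+"; sym[ch == "up"] <- "-"
  }
  new_signature(das$event_id, sym, dataset, sf_gene)
}

#' Splicing signature of a disease dataset, oriented by SF direction
#'
#' With the SF expressed up in disease, an event more included in disease is
#' `+` and one less included is `-`; with the SF down the mapping flips. An
#' undetermined SF direction yields no signature (`NULL`, with a message):
#' the SF is skipped.
#'
#' @param das a `das` result for the disease dataset (case = disease).
#' @param sf_dir `"up"`, `"down"` or `"undetermined"` from [sf_direction()].
#' @param dataset,sf_gene optional provenance labels.
#' @param dpsi_threshold,q_threshold change-call thresholds.
#' @return a `signature` data.frame, or `NULL` when `sf_dir` is
#'   undetermined.
#' @export
disease_signature <- function(das, sf_dir, dataset = NA_character_,
                              sf_gene = NA_character_,
                              dpsi_threshold = 0.05, q_threshold = 0.05) {
  if (sf_dir == "undetermined") {
    message("SF direction undetermined; skipping")
    return(NULL)
  }
  if (!sf_dir %in% c("up", "down")) stop("sf_dir must be up/down")
  ch <- event_change(das, dpsi_threshold, q_threshold)
  sym <- rep("0", length(ch))
  if (sf_dir == "up") {
    sym[ch == "up"] <- "+"; sym[ch == "down"] <- "-"
  } else {
    sym[ch == "down"] <- "+"; sym[ch == "up"] <- "-"
  }
  new_signature(das$event_id, sym, dataset, sf_gene)
}

#' Compare a perturbation signature with a disease signature
#'
#' Tabulates the 3x3 contingency table of symbols over the common events,
#' collapses it into 2x2 tables for `++` and `--` agreement, and tests each
#' by a one-sided (greater) Fisher exact test. An SF is a candidate when
#' both tests (rule `"both"`, default) or either test (rule `"either"`)
#' fall below `alpha`.
#'
#' @param sig_perturb,sig_disease `signature` data.frames.
#' @param alpha significance level (default 0.05).
#' @param rule `"both"` or `"either"`.
#' @return a `signature_comparison` list: `sf_gene`, `dataset`, `table`
#'   (3x3, rows = perturbation, cols = disease), `n_pp`, `n_mm`, `p_pp`,
#'   `p_mm`, `candidate`, `n_common`.
#' @export
compare_signatures <- function(sig_perturb, sig_disease, alpha = 0.05,
                               rule = c("both", "either")) {
  rule <- match.arg(rule)
  common <- intersect(sig_perturb$event_id, sig_disease$event_id)
  if (!length(common)) stop("no common events between the signatures")
  sp <- sig_perturb$symbol[match(common, sig_perturb$event_id)]
  sd <- sig_disease$symbol[match(common, sig_disease$event_id)]
  lev <- c("+", "-", "0")
  tab <- table(factor(sp, lev), factor(sd, lev))
  collapse_p <- function(sym) {
    a <- tab[sym, sym]
    b <- sum(tab[sym, ]) - a
    c_ <- sum(tab[, sym]) - a
    d <- sum(tab) - a - b - c_
    fisher.test(matrix(c(a, b, c_, d), 2L, 2L, byrow = TRUE),
                alternative = "greater")$p.value
  }
  p_pp <- collapse_p("+")
  p_mm <- collapse_p("-")
  candidate <- if (rule == "both") p_pp < alpha && p_mm < alpha
               else p_pp < alpha || p_mm < alpha
  structure(list(sf_gene = attr(sig_perturb, "sf_gene"),
                 dataset = attr(sig_perturb, "dataset"),
                 table = tab, n_pp = tab["+", "+"], n_mm = tab["-", "-"],
                 p_pp = p_pp, p_mm = p_mm, candidate = candidate,
                 n_common = length(common), alpha = alpha, rule = rule),
            class = "signature_comparison")
}

#' @export
print.signature_comparison <- function(x, ...) {
  cat("signature comparison", if (!is.na(x$sf_gene)) paste0("(", x$sf_gene, ")"),
      ":", x$n_common, "common events\n")
  print(x$table)
  cat("  ++:", x$n_pp, "p =", signif(x$p_pp, 3),
      "  --:", x$n_mm, "p =", signif(x$p_mm, 3),
      "  candidate:", x$candidate, "(rule:", x$rule, ")\n")
  invisible(x)
}

#' Attribute conserved events to candidate splicing factors
#'
#' An SF is listed for a conserved event iff the event's symbol in the SF's
#' perturbation signature is non-zero and equals its symbol in the disease
#' signature (a `++` or `--` agreement).
#'
#' @param conserved_event_ids event ids of the conserved events.
#' @param perturb_signatures named list of perturbation `signature` objects
#'   (names = SF genes).
#' @param disease_signatures a single disease `signature`, or a named list
#'   parallel to `perturb_signatures` (one disease signature per SF, since
#'   the disease signature is oriented by each SF's expression direction).
#' @return named list mapping each SF to the character vector of attributed
#'   event ids (SFs with no attribution are dropped).
#' @export
conserved_event_regulators <- function(conserved_event_ids,
                                       perturb_signatures,
                                       disease_signatures) {
  single <- inherits(disease_signatures, "signature")
  out <- list()
  for (sf in names(perturb_signatures)) {
    sp <- perturb_signatures[[sf]]
    sd <- if (single) disease_signatures else disease_signatures[[sf]]
    if (is.null(sd)) next
    ids <- intersect(conserved_event_ids,
                     intersect(sp$event_id, sd$event_id))
    if (!length(ids)) next
    a <- sp$symbol[match(ids, sp$event_id)]
    b <- sd$symbol[match(ids, sd$event_id)]
    hit <- ids[a != "0" & a == b]
    if (length(hit)) out[[sf]] <- hit
  }
  out
}
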