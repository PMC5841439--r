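# Term enrichment by Fisher's exact test with an odds-ratio-threshold null:
# H0 states that the odds ratio is below the threshold (natural-log reading
# of "log odds ratio < 1", i.e. OR < e), so the p-value is the upper tail of
# Fisher's noncentral hypergeometric distribution at that odds ratio.

#' Read a term-annotation table
#'
#' @param path TSV with columns `term_id`, `term_name`, `gene` (one gene per
#'   row).
#' @return a data.frame of class `term_annotation`.
#' @export
read_terms <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  stopifnot(all(c("term_id", "term_name", "gene") %in% names(df)))
  class(df) <- c("term_annotation", "data.frame")
  df
}

#' Term enrichment of a foreground gene set
#'
#' For each term the 2x2 table of foreground membership against term
#' annotation is built over the background, and the one-sided p-value is
#' computed under the noncentral (odds ratio = `or_null_threshold`) Fisher
#' null; `or_null_threshold = 1` recovers the central one-sided Fisher test.
#' The conditional-MLE log odds ratio is reported. Terms with no annotated
#' gene in the background are skipped.
#'
#' @param foreground character vector of genes (must be a subset of
#'   `background`).
#' @param background character vector of background genes.
#' @param terms a `term_annotation` data.frame ([read_terms()]).
#' @param or_null_threshold odds-ratio threshold of the null hypothesis
#'   (default `exp(1)`).
#' @param alpha significance level on the raw p-value (default 0.05).
#' @return a data.frame of class `enrichment_result`: `term_id`,
#'   `term_name`, `fg_in`, `fg_size`, `bg_in`, `bg_size`, `log_odds_ratio`,
#'   `p`, `q` (BH across terms, informational), `significant` (`p < alpha`).
#' @export
enrich <- function(foreground, background, terms,
                   or_null_threshold = exp(1), alpha = 0.05) {
  foreground <- unique(foreground)
  background <- unique(background)
  if (!all(foreground %in% background))
    stop("foreground must be a subset of the background")
  if (length(background) <= length(foreground))
    stop("background must be larger than the foreground")
  rows <- list()
  for (tid in unique(terms$term_id)) {
    tt <- terms[terms$term_id == tid, , drop = FALSE]
    tg <- intersect(unique(tt$gene), background)
    if (!length(tg)) next
    fg_in <- sum(foreground %in% tg)
    fg_out <- length(foreground) - fg_in
    bg_in <- length(tg) - fg_in
    bg_out <- length(background) - length(foreground) - bg_in
    tab <- matrix(c(fg_in, fg_out, bg_in, bg_out), 2L, 2L, byrow = TRUE)
    ft <- fisher.test(tab, or = or_null_threshold, alternative = "greater")
    est <- fisher.test(tab)$estimate
    rows[[length(rows) + 1L]] <- data.frame(
      term_id = tid, term_name = tt$term_name[1L], fg_in = fg_in,
      fg_size = length(foreground), bg_in = length(tg),
      bg_size = length(background), log_odds_ratio = log(unname(est)),
      p = ft$p.value, stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no term overlaps the background")
  res <- do.call(rbind, rows)
  res$q <- bh_adjust(res$p)
  res$significant <- res$p < alpha
  res <- res[order(res$p), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("enrichment_result", "data.frame")
  res
}
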