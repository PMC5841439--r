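# Differential alternative splicing: per-event beta-binomial LRT, pooled
# PSI estimates, BH adjustment, and the |dPSI| / q significance call.

#' Pooled percent-spliced-in estimate for one group
#'
#' `Psi = sum(n_inc) / sum(n_inc + n_exc)`, pooling counts across the
#' group's samples (depth-weighted).
#'
#' @param n_inc,n_exc per-sample counts for one event in one group.
#' @return Psi in `[0, 1]`.
#' @export
estimate_psi <- function(n_inc, n_exc) {
  tot <- sum(n_inc) + sum(n_exc)
  if (tot == 0) stop("PSI undefined: total count is zero")
  sum(n_inc) / tot
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment; a thin validated wrapper around
#' [stats::p.adjust()]. `NA` entries (non-converged events) are excluded
#' from the number of tested hypotheses and returned as `NA`.
#'
#' @param p numeric vector of p-values in `[0, 1]` (NA allowed).
#' @return q-values in the input order.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  q[ok] <- p.adjust(p[ok], method = "BH")
  q
}

#' Test differential alternative splicing across events
#'
#' The central fitting function. For every event with adequate coverage in
#' both groups it fits null and alternative beta-binomial models, computes
#' the likelihood-ratio statistic and p-value, pooled PSI per group and
#' `dPSI = Psi(case) - Psi(control)`, adjusts p-values by Benjamini-Hochberg
#' over the converged events, and flags significance at
#' `|dPSI| > dpsi_threshold` (strict) and `q < q_threshold` (strict).
#'
#' @param counts an `event_counts` data.frame (`event_id`, `sample_id`,
#'   `group`, `n_inc`, `n_exc`).
#' @param case,control the two group labels; `dPSI` is case minus control.
#' @param events optional `splice_events` used to attach `gene_id` and
#'   `event_type` to the results.
#' @param dpsi_threshold,q_threshold significance thresholds (defaults 0.05
#'   and 0.05).
#' @param min_coverage an event is tested only if every group has total
#'   count at least this (default 10).
#' @param dispersion `"common"` (default) shares one precision across all
#'   events ([common_precision()], with both per-event models fitted at that
#'   value), the moderation that keeps the test calibrated and powered at
#'   small group sizes; `"per_event"` profiles the precision under each
#'   event's own null model instead.
#' @return an object of class `das`: a data.frame with one row per tested
#'   event (`event_id`, `gene_id`, `event_type`, `psi_case`, `psi_control`,
#'   `delta_psi`, `lrt`, `p`, `q`, `significant`) and attributes recording
#'   thresholds, group labels, and events excluded by the coverage filter or
#'   by non-convergence.
#' @export
das_test <- function(counts, case, control, events = NULL,
                     dpsi_threshold = 0.05, q_threshold = 0.05,
                     min_coverage = 10,
                     dispersion = c("common", "per_event")) {
  dispersion <- match.arg(dispersion)
  stopifnot(all(c("event_id", "sample_id", "group", "n_inc", "n_exc") %in%
                  names(counts)))
  counts <- counts[counts$group %in% c(case, control), , drop = FALSE]
  if (!nrow(counts)) stop("no samples in the requested groups")
  theta_common <- if (dispersion == "common")
    common_precision(counts, case, control) else NULL
  ids <- unique(counts$event_id)
  rows <- vector("list", length(ids))
  n_lowcov <- 0L
  for (i in seq_along(ids)) {
    sub <- counts[counts$event_id == ids[i], , drop = FALSE]
    ca <- sub[sub$group == case, , drop = FALSE]
    co <- sub[sub$group == control, , drop = FALSE]
    cov_ca <- sum(ca$n_inc + ca$n_exc)
    cov_co <- sum(co$n_inc + co$n_exc)
    if (cov_ca < min_coverage || cov_co < min_coverage) {
      n_lowcov <- n_lowcov + 1L
      next
    }
    psi_ca <- estimate_psi(ca$n_inc, ca$n_exc)
    psi_co <- estimate_psi(co$n_inc, co$n_exc)
    lrt <- lrt_event(sub$n_inc, sub$n_exc,
                     ifelse(sub$group == case, "case", "control"),
                     theta_fix = theta_common)
    rows[[i]] <- data.frame(
      event_id = ids[i], psi_case = psi_ca, psi_control = psi_co,
      delta_psi = psi_ca - psi_co, lrt = lrt$stat, p = lrt$p_value,
      stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) stop("no event passed the coverage filter")
  res <- do.call(rbind, rows)
  res$q <- bh_adjust(res$p)
  res$significant <- !is.na(res$q) & abs(res$delta_psi) > dpsi_threshold &
    res$q < q_threshold
  if (!is.null(events)) {
    m <- match(res$event_id, events$event_id)
    res$gene_id <- events$gene_id[m]
    res$event_type <- events$event_type[m]
    res <- res[, c("event_id", "gene_id", "event_type", "psi_case",
                   "psi_control", "delta_psi", "lrt", "p", "q",
                   "significant")]
  }
  rownames(res) <- NULL
  structure(res,
            class = c("das", "data.frame"),
            case = case, control = control,
            dpsi_threshold = dpsi_threshold, q_threshold = q_threshold,
            n_low_coverage = n_lowcov,
            n_nonconverged = sum(is.na(res$p)),
            dispersion = dispersion, theta_common = theta_common)
}

#' Re-apply significance thresholds and tally DAS events per type
#'
#' @param das a `das` result.
#' @param dpsi_threshold,q_threshold strict thresholds (`|dPSI| >` and
#'   `q <`).
#' @return a list with `records` (the `das` object with refreshed
#'   `significant` flags) and `summary` (a data.frame of significant-event
#'   counts per event type).
#' @export
call_das <- function(das, dpsi_threshold = 0.05, q_threshold = 0.05) {
  das$significant <- !is.na(das$q) & abs(das$delta_psi) > dpsi_threshold &
    das$q < q_threshold
  attr(das, "dpsi_threshold") <- dpsi_threshold
  attr(das, "q_threshold") <- q_threshold
  if (!is.null(das$event_type)) {
    tab <- table(factor(das$event_type[das$significant],
                        levels = EVENT_TYPES))
    summ <- data.frame(event_type = names(tab), n_das = as.integer(tab),
                       stringsAsFactors = FALSE)
  } else {
    summ <- data.frame(event_type = "all", n_das = sum(das$significant),
                       stringsAsFactors = FALSE)
  }
  list(records = das, summary = summ)
}

#' @export
print.das <- function(x, ...) {
  cat("DAS analysis:", nrow(x), "events tested (",
      attr(x, "case"), "vs", attr(x, "control"), ")\n")
  cat("  significant (|dPSI| >", attr(x, "dpsi_threshold"), ", q <",
      attr(x, "q_threshold"), "):", sum(x$significant, na.rm = TRUE), "\n")
  if (attr(x, "n_low_coverage") > 0)
    cat("  excluded by coverage filter:", attr(x, "n_low_coverage"), "\n")
  if (attr(x, "n_nonconverged") > 0)
    cat("  non-converged (p = NA):", attr(x, "n_nonconverged"), "\n")
  print(head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("  ...", nrow(x) - 6, "more rows\n")
  invisible(x)
}

#' @method summary das
#' @export
summary.das <- function(object, ...) {
  cd <- call_das(object, attr(object, "dpsi_threshold"),
                 attr(object, "q_threshold"))
  out <- list(n_tested = nrow(object),
              n_significant = sum(object$significant, na.rm = TRUE),
              per_type = cd$summary,
              case = attr(object, "case"),
              control = attr(object, "control"))
  class(out) <- "summary.das"
  out
}

#' @export
print.summary.das <- function(x, ...) {
  cat("DAS summary (", x$case, "vs", x$control, "):", x$n_significant,
      "of", x$n_tested, "events significant\n")
  print(x$per_type, row.names = FALSE)
  invisible(x)
}

#' Volcano-style plot of a DAS result
#'
#' dPSI against -log10(q); significant events highlighted.
#'
#' @param x a `das` object.
#' @param ... passed to [graphics::plot()].
#' @method plot das
#' @export
plot.das <- function(x, ...) {
  q <- pmax(x$q, 1e-300)
  graphics::plot(x$delta_psi, -log10(q), xlab = expression(Delta * Psi),
                 ylab = expression(-log[10](q)),
                 col = ifelse(x$significant, "firebrick", "grey40"),
                 pch = 16, cex = 0.6, ...)
  graphics::abline(v = c(-1, 1) * attr(x, "dpsi_threshold"), lty = 2)
  graphics::abline(h = -log10(attr(x, "q_threshold")), lty = 2)
  invisible(x)
}

#' Write a DAS result to TSV
#' @param das a `das` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_das <- function(das, path) {
  write.table(as.data.frame(das), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a DAS result from TSV
#' @param path path written by [write_das()].
#' @param case,control,dpsi_threshold,q_threshold metadata to re-attach.
#' @return a `das` object.
#' @export
read_das <- function(path, case = "case", control = "control",
                     dpsi_threshold = 0.05, q_threshold = 0.05) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  structure(df, class = c("das", "data.frame"), case = case,
            control = control, dpsi_threshold = dpsi_threshold,
            q_threshold = q_threshold, n_low_coverage = 0L,
            n_nonconverged = sum(is.na(df$p)))
}
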