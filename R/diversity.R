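#' Hill number of order q
#'
#' Effective number of taxa \code{D(q) = (sum p_i^q)^(1/(1-q))}, with the
#' limit \code{exp(-sum p_i log p_i)} at q = 1 (the exponential of Shannon
#' entropy); q = 0 is richness and q = 2 the inverse Simpson index. Zeros
#' are excluded from the sums. Near q = 1 (within 1e-6) the limit form is
#' used, keeping D continuous in q.
#'
#' @param p relative-abundance vector (sums to 1, tolerance 1e-9).
#' @param q order, >= 0.
#' @return the diversity; 0 (with attribute \code{empty = TRUE}) for an
#'   empty or all-zero vector.
#' @examples
#' hillNumber(rep(0.25, 4), 0)  # 4
#' hillNumber(c(0.6, 0.3, 0.1), 2)  # 1 / 0.46
#' @export
hillNumber <- function(p, q) {
  stopifnot(q >= 0, all(p >= 0))
  p <- p[p > 0]
  if (!length(p)) {
    out <- 0
    attr(out, "empty") <- TRUE
    return(out)
  }
  if (abs(sum(p) - 1) > 1e-9)
    stop("p must sum to 1 (got ", format(sum(p)), ")")
  if (abs(q - 1) < 1e-6)
    exp(-sum(p * log(p)))
  else
    sum(p^q)^(1 / (1 - q))
}

#' Coefficient of variation (percent)
#'
#' \code{100 * sd / mean} with the sample (n - 1) standard deviation — the
#' convention for small inter-laboratory panels.
#'
#' @param values numeric vector, length >= 2.
#' @return CV in percent; \code{NA} with attribute
#'   \code{undefined = TRUE} when the mean is 0.
#' @examples
#' coefficientOfVariation(c(40, 60))
#' @export
coefficientOfVariation <- function(values) {
  stopifnot(length(values) >= 2L)
  m <- mean(values)
  if (m == 0) {
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    return(out)
  }
  100 * stats::sd(values) / m
}

#' Per-sample scalar metrics
#'
#' One row per sample: read count and Hill numbers q = 0, 1, 2 computed on
#' the table as given (call once on the ASV-level and once on the
#' species-aggregated table to mirror genetic and taxonomic richness).
#' Extra per-sample covariates (e.g. DNA concentration in ng/ul) can be
#' appended by name.
#'
#' @param table an [AbundanceTable-class]; counts are converted to
#'   fractions internally for the Hill numbers.
#' @param prefix metric-name prefix, e.g. \code{"asv"} or \code{"species"}.
#' @param extra optional data.frame of extra metric columns, rownames =
#'   sample keys.
#' @return data.frame (rows = samples) with the sample metadata columns
#'   followed by the metric columns.
#' @export
metricTable <- function(table, prefix = "asv", extra = NULL) {
  stopifnot(is(table, "AbundanceTable"))
  rel <- if (abundMode(table) == "counts") toRelative(table) else table
  m <- abundValues(rel)
  reads <- if (abundMode(table) == "counts") colSums(abundValues(table))
           else rep(NA_real_, ncol(m))
  met <- data.frame(
    reads = reads,
    q0 = apply(m, 2, function(p) as.numeric(hillNumber(p, 0))),
    q1 = apply(m, 2, function(p) as.numeric(hillNumber(p, 1))),
    q2 = apply(m, 2, function(p) as.numeric(hillNumber(p, 2))),
    row.names = colnames(m))
  names(met)[-1L] <- paste0(prefix, "_", c("q0", "q1", "q2"))
  out <- cbind(sampleInfo(table), met)
  if (!is.null(extra))
    out <- cbind(out, extra[rownames(out), , drop = FALSE])
  out
}

#' Cross-participant CV summary (radar-chart data)
#'
#' For each metric column and each sample type, the coefficient of
#' variation across participants. Groups with fewer than two participants
#' are skipped and listed in the \code{"skipped"} attribute.
#'
#' @param metrics data.frame from [metricTable()]; must carry
#'   \code{participant} and \code{sample_type} columns.
#' @param metric_cols names of the metric columns to summarise; defaults to
#'   all numeric columns other than \code{replicate}.
#' @return long data.frame with columns \code{sample_type}, \code{metric},
#'   \code{cv} (percent), \code{n}.
#' @export
metricCVSummary <- function(metrics, metric_cols = NULL) {
  stopifnot(all(c("participant", "sample_type") %in% names(metrics)))
  if (is.null(metric_cols)) {
    num <- vapply(metrics, is.numeric, TRUE)
    metric_cols <- setdiff(names(metrics)[num], "replicate")
  }
  rows <- list()
  skipped <- character()
  for (st in unique(metrics$sample_type)) {
    sub <- metrics[metrics$sample_type == st, , drop = FALSE]
    # one value per participant (mean over replicates)
    for (mc in metric_cols) {
      per_lab <- tapply(sub[[mc]], sub$participant, mean, na.rm = TRUE)
      per_lab <- per_lab[is.finite(per_lab)]
      if (length(per_lab) < 2L) {
        skipped <- c(skipped, sprintf("%s/%s: fewer than 2 participants", st, mc))
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        sample_type = st, metric = mc,
        cv = as.numeric(coefficientOfVariation(as.numeric(per_lab))),
        n = length(per_lab), stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sample_type = character(), metric = character(),
               cv = numeric(), n = integer())
  attr(out, "skipped") <- skipped
  out
}
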