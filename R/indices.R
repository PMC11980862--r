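index_result <- function(sample = NA_character_, index, score, coverage,
                         valid, flag = NA_character_, clamped = FALSE) {
  data.frame(sample = sample, index = index, score = score,
             coverage = coverage, valid = valid, flag = flag,
             clamped = clamped, stringsAsFactors = FALSE)
}

#' Specific Pollution Sensitivity (IPS-type) index score
#'
#' The Zelinka-Marvan abundance-weighted average of taxon sensitivities,
#' \code{raw = sum(a_j s_j v_j) / sum(a_j v_j)} over taxa with traits
#' (abundances renormalised over the covered taxa), rescaled to the 1-20
#' scale by \code{score = 4.75 * raw - 3.75} and clamped to [1, 20]. The
#' fraction of relative abundance carried by trait-covered taxa is reported
#' as \code{coverage}; results with coverage below \code{min_coverage} are
#' flagged invalid.
#'
#' @param p named relative-abundance vector (a sample column).
#' @param traits a [TraitTable-class].
#' @param min_coverage minimum trait coverage for a valid score.
#' @param sample optional sample key carried into the result.
#' @return one-row data.frame: \code{sample}, \code{index}, \code{score},
#'   \code{coverage}, \code{valid}, \code{flag}, \code{clamped}.
#' @examples
#' tt <- traitTable(c("a", "b"), s = c(5, 1), v = c(1, 1))
#' ipsScore(c(a = 0.5, b = 0.5), tt)$score   # 4.75 * 3 - 3.75
#' @export
ipsScore <- function(p, traits, min_coverage = 0.7, sample = NA_character_) {
  stopifnot(is(traits, "TraitTable"))
  covered <- intersect(names(p)[p > 0], traitTaxa(traits))
  coverage <- if (sum(p) > 0) sum(p[covered]) / sum(p) else 0
  if (!length(covered) || coverage == 0)
    return(index_result(sample, "IPS", NA_real_, 0, FALSE, "zero_coverage"))
  a <- p[covered] / sum(p[covered])
  s <- traitS(traits)[covered]
  v <- traitV(traits)[covered]
  raw <- sum(a * s * v) / sum(a * v)
  score <- 4.75 * raw - 3.75
  clamped <- score < 1 || score > 20
  score <- min(max(score, 1), 20)
  index_result(sample, "IPS", score, coverage,
               valid = coverage >= min_coverage,
               flag = if (coverage < min_coverage) "low_coverage" else
                 NA_character_,
               clamped = clamped)
}

#' Biological Diatom Index (IBD-type) profile score
#'
#' The seven-class probability-profile index: class loadings
#' \code{F_i = sum_x a_x P_xi v_x / sum_x a_x v_x} over profiled taxa, the
#' barycentre \code{B = sum(F_i c_i) / sum(F_i)} on the class scores
#' \code{c_1 < ... < c_7}, mapped affinely from \code{[c_1, c_7]} to
#' [1, 20] and clamped.
#'
#' @inheritParams ipsScore
#' @return one-row data.frame as for [ipsScore()], index \code{"IBD"}.
#' @export
ibdScore <- function(p, traits, min_coverage = 0.7, sample = NA_character_) {
  stopifnot(is(traits, "TraitTable"))
  prof <- traitProfiles(traits)
  covered <- intersect(names(p)[p > 0], rownames(prof))
  coverage <- if (sum(p) > 0) sum(p[covered]) / sum(p) else 0
  if (!length(covered) || coverage == 0)
    return(index_result(sample, "IBD", NA_real_, 0, FALSE, "zero_coverage"))
  a <- p[covered] / sum(p[covered])
  v <- traitV(traits)[covered]
  P <- prof[covered, , drop = FALSE]
  Fi <- colSums(a * v * P) / sum(a * v)
  cs <- traits@classScores
  B <- sum(Fi * cs) / sum(Fi)
  score <- 1 + (B - cs[1L]) * 19 / (cs[length(cs)] - cs[1L])
  clamped <- score < 1 || score > 20
  score <- min(max(score, 1), 20)
  index_result(sample, "IBD", score, coverage,
               valid = coverage >= min_coverage,
               flag = if (coverage < min_coverage) "low_coverage" else
                 NA_character_,
               clamped = clamped)
}

#' Index scores for every sample of a table
#'
#' @param table relative-mode [AbundanceTable-class].
#' @param traits a [TraitTable-class].
#' @param index \code{"IPS"} or \code{"IBD"}.
#' @param min_coverage minimum trait coverage for validity.
#' @return data.frame, one row per sample, sample metadata prepended.
#' @export
indexScores <- function(table, traits, index = c("IPS", "IBD"),
                        min_coverage = 0.7) {
  stopifnot(is(table, "AbundanceTable"))
  index <- match.arg(index)
  if (abundMode(table) != "relative")
    stop("indexScores requires a relative-mode table (see toRelative)")
  f <- if (index == "IPS") ipsScore else ibdScore
  m <- abundValues(table)
  res <- do.call(rbind, lapply(colnames(m), function(k)
    f(m[, k], traits, min_coverage = min_coverage, sample = k)))
  cbind(sampleInfo(table), res[, setdiff(names(res), "sample")])
}

#' Ecological status class from a 1-20 index score
#'
#' Five classes by half-open intervals: with the default boundaries,
#' scores in [17, 20] are \code{high}, [13, 17) \code{good}, [9, 13)
#' \code{moderate}, [5, 9) \code{poor} and [1, 5) \code{bad}.
#'
#' @param score_20 numeric score(s) in [1, 20].
#' @param boundaries increasing numeric(4): lower bounds of poor, moderate,
#'   good, high.
#' @return character class label(s).
#' @examples
#' ecologicalClass(c(20, 16.99, 17))
#' @export
ecologicalClass <- function(score_20, boundaries = c(5, 9, 13, 17)) {
  if (is.unsorted(boundaries, strictly = TRUE))
    stop("boundaries must be strictly increasing")
  stopifnot(all(score_20 >= 1 & score_20 <= 20, na.rm = TRUE))
  labels <- c("bad", "poor", "moderate", "good", "high")
  idx <- findInterval(score_20, c(-Inf, boundaries))
  labels[idx]
}
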