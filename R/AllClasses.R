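#' @import methods
#' @importFrom S4Vectors DataFrame
#' @import SummarizedExperiment
NULL

VALID_SAMPLE_TYPES <- c("L", "R", "M", "W")

#' DesignSpec: a machine-readable ring-trial design
#'
#' One row per experiment: an experiment id, the starting material, the
#' participating laboratories, the number of replicates per sample, and the
#' calibrated sample types handled (lake biofilm \code{L}, river biofilm
#' \code{R}, mock community \code{M}, water blank \code{W}).
#'
#' @slot experiments data.frame with columns \code{id}, \code{material},
#'   \code{replicates} and list-columns \code{participants},
#'   \code{sample_types}.
#' @seealso [designSpec()], [studyDesign()], [expandDesign()]
#' @export
setClass("DesignSpec", representation(experiments = "data.frame"))

setValidity("DesignSpec", function(object) {
  ex <- object@experiments
  msgs <- character()
  need <- c("id", "material", "participants", "replicates", "sample_types")
  if (!all(need %in% names(ex)))
    return(paste("experiments must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(ex$id))
    msgs <- c(msgs, paste0("duplicate experiment id: ",
                           paste(unique(ex$id[duplicated(ex$id)]), collapse = ", ")))
  for (i in seq_len(nrow(ex))) {
    if (ex$replicates[[i]] < 1L)
      msgs <- c(msgs, sprintf("experiment %s: replicates must be >= 1", ex$id[[i]]))
    p <- ex$participants[[i]]
    if (anyDuplicated(p))
      msgs <- c(msgs, sprintf("experiment %s: duplicated participant id", ex$id[[i]]))
    st <- ex$sample_types[[i]]
    if (length(st) == 0L)
      msgs <- c(msgs, sprintf("experiment %s: sample_types must be non-empty", ex$id[[i]]))
    if (!all(st %in% VALID_SAMPLE_TYPES))
      msgs <- c(msgs, sprintf("experiment %s: sample_types must be a subset of {L,R,M,W}",
                              ex$id[[i]]))
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' AbundanceTable: taxa x samples abundances with sample metadata
#'
#' A [SummarizedExperiment::SummarizedExperiment] whose single assay
#' (\code{"abund"}) holds non-negative read counts or relative abundances
#' (fractions), with the ring-trial sample metadata (experiment, participant,
#' sample type, replicate, sequencing flags) in \code{colData}. Sample
#' (column) names are manifest keys of the form \code{"E1/A/L/1"}.
#'
#' @slot mode either \code{"counts"} or \code{"relative"}. In relative mode
#'   every non-empty sample column sums to 1 (tolerance 1e-9).
#' @seealso [AbundanceTable()], [toRelative()], [abundValues()]
#' @export
setClass("AbundanceTable",
         contains = "SummarizedExperiment",
         representation(mode = "character"))

setValidity("AbundanceTable", function(object) {
  m <- assay(object, "abund")
  msgs <- character()
  if (!object@mode %in% c("counts", "relative"))
    msgs <- c(msgs, "mode must be 'counts' or 'relative'")
  if (anyDuplicated(rownames(m)))
    msgs <- c(msgs, "taxon ids must be unique")
  if (any(m < 0))
    msgs <- c(msgs, "abundance values must be non-negative")
  if (identical(object@mode, "relative") && ncol(m) > 0L) {
    cs <- colSums(m)
    bad <- which(cs > 0 & abs(cs - 1) > 1e-9)
    if (length(bad))
      msgs <- c(msgs, paste0("relative-mode columns must sum to 1 (or 0): ",
                             paste(colnames(m)[bad], collapse = ", ")))
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' TraitTable: per-taxon index traits
#'
#' Sensitivity \code{s} on the 1-5 scale, indicator (stenoecy) weight
#' \code{v} in \{1,2,3\}, and optionally a probability profile over seven
#' water-quality classes with increasing class scores, as used by the
#' profile-based diatom index.
#'
#' @slot taxa character taxon ids (unique).
#' @slot s numeric sensitivities in [1, 5].
#' @slot v numeric indicator weights in \{1, 2, 3\}.
#' @slot profiles numeric matrix (taxa x 7) of class probabilities, or a
#'   0-row matrix when no profiles are available; rows sum to 1 (tol 1e-6).
#' @slot classScores numeric(7), strictly increasing class scores.
#' @seealso [traitTable()], [readTraitTable()], [ipsScore()], [ibdScore()]
#' @export
setClass("TraitTable",
         representation(taxa = "character", s = "numeric", v = "numeric",
                        profiles = "matrix", classScores = "numeric"))

setValidity("TraitTable", function(object) {
  msgs <- character()
  n <- length(object@taxa)
  if (anyDuplicated(object@taxa))
    msgs <- c(msgs, "taxon ids must be unique")
  if (length(object@s) != n || length(object@v) != n)
    msgs <- c(msgs, "s and v must have one value per taxon")
  bad_s <- object@taxa[object@s < 1 | object@s > 5]
  if (length(bad_s))
    msgs <- c(msgs, paste0("sensitivity s out of [1,5] for: ",
                           paste(bad_s, collapse = ", ")))
  bad_v <- object@taxa[!object@v %in% c(1, 2, 3)]
  if (length(bad_v))
    msgs <- c(msgs, paste0("indicator value v not in {1,2,3} for: ",
                           paste(bad_v, collapse = ", ")))
  if (nrow(object@profiles) > 0L) {
    if (ncol(object@profiles) != length(object@classScores))
      msgs <- c(msgs, "profiles must have one column per class score")
    rs <- rowSums(object@profiles)
    bad <- rownames(object@profiles)[abs(rs - 1) > 1e-6]
    if (length(bad))
      msgs <- c(msgs, paste0("profile rows must sum to 1: ",
                             paste(bad, collapse = ", ")))
    if (any(object@profiles < 0))
      msgs <- c(msgs, "profile probabilities must be non-negative")
  }
  if (is.unsorted(object@classScores, strictly = TRUE))
    msgs <- c(msgs, "classScores must be strictly increasing")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})
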