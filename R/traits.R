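#' Construct a TraitTable
#'
#' @param taxa character taxon ids.
#' @param s sensitivities in [1, 5] (Zelinka-Marvan style scale).
#' @param v indicator (stenoecy) weights in \{1, 2, 3\}.
#' @param profiles optional taxa x classes probability matrix (rownames are
#'   taxon ids; rows sum to 1, tolerance 1e-6) for the profile-based index.
#' @param classScores increasing class scores, default \code{1:7}.
#' @return a [TraitTable-class].
#' @examples
#' tt <- traitTable(c("a", "b"), s = c(5, 1), v = c(1, 1))
#' traitTaxa(tt)
#' @export
traitTable <- function(taxa, s, v, profiles = NULL, classScores = 1:7) {
  if (is.null(profiles) || nrow(profiles) == 0L) {
    profiles <- matrix(numeric(), 0L, length(classScores))
  } else {
    profiles <- as.matrix(profiles)
    if (is.null(rownames(profiles)))
      rownames(profiles) <- taxa
    colnames(profiles) <- NULL
    missing <- setdiff(rownames(profiles), taxa)
    if (length(missing))
      stop("profile rows for unknown taxa: ", paste(missing, collapse = ", "))
  }
  new("TraitTable", taxa = as.character(taxa), s = as.numeric(s),
      v = as.numeric(v), profiles = profiles,
      classScores = as.numeric(classScores))
}

#' @describeIn traitTable taxon ids covered by the table.
#' @param x a TraitTable.
#' @export
traitTaxa <- function(x) x@taxa

#' @describeIn traitTable sensitivities named by taxon.
#' @export
traitS <- function(x) stats::setNames(x@s, x@taxa)

#' @describeIn traitTable indicator weights named by taxon.
#' @export
traitV <- function(x) stats::setNames(x@v, x@taxa)

#' @describeIn traitTable class-probability profiles (may have 0 rows).
#' @export
traitProfiles <- function(x) x@profiles

setMethod("show", "TraitTable", function(object) {
  cat(sprintf("TraitTable: %d taxa, %d with class profiles (%d classes)\n",
              length(object@taxa), nrow(object@profiles),
              length(object@classScores)))
  invisible(NULL)
})

#' Generate a synthetic trait table
#'
#' Draws a sensitivity \code{s} uniformly on [1, 5] and an indicator weight
#' \code{v} from \{1, 2, 3\} for each taxon, plus a 7-class probability
#' profile peaked at the class corresponding to \code{s} (a taxon of
#' sensitivity 5 loads on the best class, sensitivity 1 on the worst).
#' This is a synthetic stand-in for national trait databases, sufficient to
#' exercise every index computation; it carries no real autecological
#' information.
#'
#' @param taxa character taxon ids.
#' @param seed integer seed.
#' @param concentration how peaked profiles are around their class centre
#'   (Gaussian kernel sd in class units; smaller = more peaked).
#' @return a [TraitTable-class] with profiles.
#' @export
syntheticTraitTable <- function(taxa, seed = 1L, concentration = 0.6) {
  set.seed(as.integer(seed))
  n <- length(taxa)
  s <- round(stats::runif(n, 1, 5), 1)
  v <- sample(c(1, 2, 3), n, replace = TRUE, prob = c(0.5, 0.35, 0.15))
  centre <- 1 + (s - 1) * 1.5          # map s in [1,5] to class in [1,7]
  prof <- t(vapply(centre, function(cc) {
    w <- exp(-((1:7 - cc)^2) / (2 * concentration^2))
    w / sum(w)
  }, numeric(7)))
  rownames(prof) <- taxa
  traitTable(taxa, s, v, profiles = prof)
}
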