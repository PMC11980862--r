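#' @include AllClasses.R
NULL

#' Build a manifest key
#'
#' Manifest keys are the 4-tuple \code{experiment/participant/sample_type/
#' replicate} joined with \code{"/"}, e.g. \code{"E2/G/L/1"}. They name
#' sample columns in every table the pipeline touches, making joins across
#' modules unambiguous.
#'
#' @param experiment,participant,sample_type,replicate vectors, recycled to
#'   a common length.
#' @return character vector of keys.
#' @export
unitKey <- function(experiment, participant, sample_type, replicate) {
  paste(experiment, participant, sample_type, replicate, sep = "/")
}

#' Parse manifest keys into their components
#'
#' @param keys character vector of \code{"E1/A/L/1"}-style keys.
#' @return data.frame with columns \code{experiment}, \code{participant},
#'   \code{sample_type}, \code{replicate} (integer) and \code{key}.
#' @export
parseUnitKey <- function(keys) {
  parts <- strsplit(keys, "/", fixed = TRUE)
  bad <- lengths(parts) != 4L
  if (any(bad))
    stop("malformed manifest key(s): ", paste(keys[bad], collapse = ", "))
  data.frame(
    experiment  = vapply(parts, `[`, "", 1L),
    participant = vapply(parts, `[`, "", 2L),
    sample_type = vapply(parts, `[`, "", 3L),
    replicate   = as.integer(vapply(parts, `[`, "", 4L)),
    key = keys,
    stringsAsFactors = FALSE
  )
}

#' Construct an AbundanceTable
#'
#' @param values non-negative numeric matrix, taxa as rows (rownames = taxon
#'   ids), samples as columns (colnames = manifest keys).
#' @param sampleData optional data.frame of per-sample metadata, one row per
#'   column of \code{values}; when omitted, metadata are parsed from the
#'   column-name keys.
#' @param mode \code{"counts"} (reads) or \code{"relative"} (fractions in
#'   [0,1]; each non-empty column must sum to 1, tolerance 1e-9).
#' @return an [AbundanceTable-class] object.
#' @examples
#' m <- matrix(c(30, 70, 10, 90), nrow = 2,
#'             dimnames = list(c("t1", "t2"), c("E1/A/L/1", "E1/B/L/1")))
#' at <- AbundanceTable(m, mode = "counts")
#' abundMode(at)
#' @export
AbundanceTable <- function(values, sampleData = NULL,
                           mode = c("counts", "relative")) {
  mode <- match.arg(mode)
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    stop("values must have taxon ids as rownames")
  if (is.null(colnames(values)))
    stop("values must have sample keys as colnames")
  neg <- which(values < 0, arr.ind = TRUE)
  if (nrow(neg))
    stop(sprintf("negative abundance at taxon '%s', sample '%s'",
                 rownames(values)[neg[1L, 1L]], colnames(values)[neg[1L, 2L]]))
  if (is.null(sampleData)) {
    sampleData <- parseUnitKey(colnames(values))
  }
  cd <- DataFrame(sampleData, row.names = colnames(values))
  se <- SummarizedExperiment(assays = list(abund = values), colData = cd)
  new("AbundanceTable", se, mode = mode)
}

#' @describeIn AbundanceTable the abundance matrix (taxa x samples).
#' @param x an AbundanceTable.
#' @export
abundValues <- function(x) assay(x, "abund")

#' @describeIn AbundanceTable the storage mode, \code{"counts"} or
#'   \code{"relative"}.
#' @export
abundMode <- function(x) x@mode

#' @describeIn AbundanceTable taxon ids (rownames).
#' @export
taxonIds <- function(x) rownames(x)

#' @describeIn AbundanceTable sample manifest keys (colnames).
#' @export
sampleKeys <- function(x) colnames(x)

#' @describeIn AbundanceTable per-sample metadata as a plain data.frame.
#' @export
sampleInfo <- function(x) as.data.frame(colData(x))

setMethod("show", "AbundanceTable", function(object) {
  cat(sprintf("AbundanceTable: %d taxa x %d samples [%s mode]\n",
              nrow(object), ncol(object), object@mode))
  if (ncol(object)) {
    info <- colData(object)
    if ("experiment" %in% names(info))
      cat("  experiments:", paste(unique(info$experiment), collapse = ", "), "\n")
    if ("sample_type" %in% names(info))
      cat("  sample types:", paste(unique(info$sample_type), collapse = ", "), "\n")
  }
  invisible(NULL)
})

# subset while keeping the class and mode intact; relative tables are
# renormalised by the caller if columns change composition (rows subsetting
# breaks the sum-to-1 invariant, so return counts-like raw matrix instead).
subsetSamples <- function(x, keys) {
  stopifnot(all(keys %in% colnames(x)))
  AbundanceTable(abundValues(x)[, keys, drop = FALSE],
                 sampleData = as.data.frame(colData(x)[keys, , drop = FALSE]),
                 mode = x@mode)
}
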