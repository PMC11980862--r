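#' Create a ring-trial design specification
#'
#' @param experiments list of experiment records; each a list with elements
#'   \code{id} (e.g. "E1"), \code{material} ("biofilm" or "DNA"),
#'   \code{participants} (character vector of lab codes), \code{replicates}
#'   (positive integer) and \code{sample_types} (subset of L, R, M, W).
#' @return a [DesignSpec-class] object.
#' @examples
#' d <- designSpec(list(list(id = "E1", material = "biofilm",
#'                           participants = LETTERS[1:3], replicates = 1,
#'                           sample_types = c("L", "R", "M", "W"))))
#' nrow(expandDesign(d))
#' @export
designSpec <- function(experiments) {
  ex <- data.frame(
    id = vapply(experiments, function(e) as.character(e$id), ""),
    material = vapply(experiments, function(e) as.character(e$material), ""),
    replicates = vapply(experiments, function(e) as.integer(e$replicates), 0L),
    stringsAsFactors = FALSE
  )
  ex$participants <- lapply(experiments, function(e) as.character(e$participants))
  ex$sample_types <- lapply(experiments, function(e) as.character(e$sample_types))
  new("DesignSpec", experiments = ex)
}

setMethod("show", "DesignSpec", function(object) {
  ex <- object@experiments
  cat(sprintf("DesignSpec with %d experiment(s)\n", nrow(ex)))
  for (i in seq_len(nrow(ex)))
    cat(sprintf("  %s [%s]: %d participant(s) x %d type(s) x %d replicate(s)\n",
                ex$id[[i]], ex$material[[i]], length(ex$participants[[i]]),
                length(ex$sample_types[[i]]), ex$replicates[[i]]))
  invisible(NULL)
})

#' The study's experimental design
#'
#' The four cross-laboratory experiments plus the reference laboratory's own
#' replicates: proficiency tests E1 (DNA extraction) and E2 (PCR
#' amplification) with 17 participants, one replicate, four calibrated
#' sample types (L, R, M, W); method-comparison experiments E3 and E4 with 9
#' participants and 3 replicates; and a REF pseudo-experiment in which the
#' reference laboratory ("RL") processes all four sample types in
#' triplicate. Expanding this design yields the study's 364 amplicon pools.
#'
#' The nine method-comparison labs are anonymised in the source data; any
#' nine of the seventeen reproduce the design totals, and a fixed subset is
#' used here for determinism.
#'
#' @return a [DesignSpec-class].
#' @examples
#' nrow(expandDesign(studyDesign()))  # 364
#' @export
studyDesign <- function() {
  p17 <- LETTERS[1:17]           # labs A..Q
  p9  <- c("D", "E", "F", "I", "K", "M", "N", "O", "P")
  lrmw <- c("L", "R", "M", "W")
  designSpec(list(
    list(id = "E1", material = "biofilm", participants = p17,
         replicates = 1L, sample_types = lrmw),
    list(id = "E2", material = "DNA", participants = p17,
         replicates = 1L, sample_types = lrmw),
    list(id = "E3", material = "biofilm", participants = p9,
         replicates = 3L, sample_types = lrmw),
    list(id = "E4", material = "DNA", participants = p9,
         replicates = 3L, sample_types = lrmw),
    list(id = "REF", material = "biofilm", participants = "RL",
         replicates = 3L, sample_types = lrmw)
  ))
}

#' The study's sequencing exceptions
#'
#' Water blanks are not sequenced unless unexpected amplification was seen;
#' three such "W false positive" units were sequenced. One E2 amplicon
#' (participant G, lake sample) was too faint and was not sequenced.
#'
#' @return list with elements \code{w_exceptions} and \code{failed},
#'   character vectors of manifest keys.
#' @export
studySequencingExceptions <- function() {
  list(w_exceptions = c("E1/E/W/1", "E1/Q/W/1", "E3/O/W/1"),
       failed = "E2/G/L/1")
}

#' Expand a design into a sample manifest
#'
#' One manifest row (sample unit) per (experiment, participant, sample type,
#' replicate) combination, in that deterministic nesting order, with
#' sequencing flags initialised to \code{NA}/\code{FALSE}.
#'
#' @param design a [DesignSpec-class].
#' @return data.frame with columns \code{experiment}, \code{participant},
#'   \code{sample_type}, \code{replicate}, \code{key}, \code{sequenced},
#'   \code{false_positive_control}, \code{failed_amplicon}.
#' @examples
#' man <- expandDesign(studyDesign())
#' nrow(man)                                  # 364 amplicon pools
#' sum(man$experiment == "E1")                # 68 E1 extracts
#' @export
expandDesign <- function(design) {
  stopifnot(is(design, "DesignSpec"))
  validObject(design)
  ex <- design@experiments
  rows <- vector("list", nrow(ex))
  for (i in seq_len(nrow(ex))) {
    g <- expand.grid(replicate = seq_len(ex$replicates[[i]]),
                     sample_type = ex$sample_types[[i]],
                     participant = ex$participants[[i]],
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    g <- g[, c("participant", "sample_type", "replicate")]
    g <- g[order(match(g$participant, ex$participants[[i]]),
                 match(g$sample_type, ex$sample_types[[i]]),
                 g$replicate), , drop = FALSE]
    g$experiment <- ex$id[[i]]
    rows[[i]] <- g
  }
  man <- do.call(rbind, rows)
  if (is.null(man)) {
    man <- data.frame(experiment = character(), participant = character(),
                      sample_type = character(), replicate = integer(),
                      stringsAsFactors = FALSE)
  }
  man <- man[, c("experiment", "participant", "sample_type", "replicate")]
  man$key <- unitKey(man$experiment, man$participant, man$sample_type,
                     man$replicate)
  man$sequenced <- rep(NA, nrow(man))
  man$false_positive_control <- rep(FALSE, nrow(man))
  man$failed_amplicon <- rep(FALSE, nrow(man))
  rownames(man) <- NULL
  man
}

#' Apply the sequencing-inclusion rules to a manifest
#'
#' Water blanks (\code{W}) are sequenced only when listed as exceptions (and
#' are then flagged as false-positive controls); all other units are
#' sequenced unless their amplicon failed.
#'
#' @param units manifest data.frame from [expandDesign()].
#' @param w_exceptions manifest keys of W units that were sequenced.
#' @param failed manifest keys of non-W units whose amplicons failed.
#' @return the manifest with \code{sequenced}, \code{false_positive_control}
#'   and \code{failed_amplicon} filled in.
#' @examples
#' man <- expandDesign(studyDesign())
#' exc <- studySequencingExceptions()
#' man <- applySequencingRules(man, exc$w_exceptions, exc$failed)
#' sum(man$sequenced)  # 275 successful PCR reactions
#' @export
applySequencingRules <- function(units, w_exceptions = character(),
                                 failed = character()) {
  unknown <- setdiff(c(w_exceptions, failed), units$key)
  if (length(unknown))
    stop("unknown manifest key(s): ", paste(unknown, collapse = ", "))
  is_w <- units$sample_type == "W"
  bad_w <- setdiff(w_exceptions, units$key[is_w])
  if (length(bad_w))
    stop("w_exceptions must reference W units: ", paste(bad_w, collapse = ", "))
  units$false_positive_control <- is_w & units$key %in% w_exceptions
  units$failed_amplicon <- units$key %in% failed
  units$sequenced <- ifelse(is_w, units$false_positive_control,
                            !units$failed_amplicon)
  units
}

#' Design accounting summary
#'
#' Tallies the manifest the way the study reports it: DNA extracts per
#' extraction experiment, total amplicon pools, sequenced reactions, and
#' retained samples per experiment after setting aside the sequenced blank
#' controls.
#'
#' @param units manifest after [applySequencingRules()].
#' @return list with \code{extracts} (named, units per experiment),
#'   \code{total_pools}, \code{sequenced}, and \code{retained} (named,
#'   sequenced non-control units per experiment).
#' @export
designAccounting <- function(units) {
  if (any(is.na(units$sequenced)))
    stop("apply sequencing rules before accounting")
  retained <- units$sequenced & !units$false_positive_control
  list(
    extracts = table(units$experiment),
    total_pools = nrow(units),
    sequenced = sum(units$sequenced),
    retained = c(tapply(retained, units$experiment, sum))
  )
}
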