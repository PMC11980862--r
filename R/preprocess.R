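#' Discard non-target and unclassified taxa
#'
#' Removes rows assigned to a phylum other than the target, and rows whose
#' assignment label is \code{"<target>_unclassified"} — the post-assignment
#' cleanup applied before any abundance filtering.
#'
#' @param table an [AbundanceTable-class].
#' @param taxonomy taxonomy map data.frame (\code{taxon_id}, \code{phylum},
#'   \code{genus}, \code{species}, \code{label}).
#' @param target_phylum phylum to keep (default \code{"Bacillariophyta"}).
#' @return the filtered [AbundanceTable-class].
#' @export
discardNonTarget <- function(table, taxonomy,
                             target_phylum = "Bacillariophyta") {
  stopifnot(is(table, "AbundanceTable"))
  missing <- setdiff(taxonIds(table), taxonomy$taxon_id)
  if (length(missing))
    stop("taxon (taxa) missing from taxonomy: ", paste(missing, collapse = ", "))
  tax <- taxonomy[match(taxonIds(table), taxonomy$taxon_id), , drop = FALSE]
  drop <- tax$phylum != target_phylum |
    tax$label == paste0(target_phylum, "_unclassified")
  keep <- taxonIds(table)[!drop]
  AbundanceTable(abundValues(table)[keep, , drop = FALSE],
                 sampleData = sampleInfo(table), mode = abundMode(table))
}

#' Filter low-abundance cells
#'
#' Per sample cell: a count is zeroed when it is below \code{min_reads}
#' \emph{and} below \code{min_fraction} of the sample's pre-filter read
#' total (the literal conjunctive reading of the removal rule; a
#' disjunctive reading is available via \code{rule = "or"}, and a whole-row
#' variant via \code{per = "taxon"}, which tests the taxon's maximum cell
#' against both conditions). Taxa left all-zero are dropped. Empty samples
#' (total 0) are retained untouched and reported via the
#' \code{"empty_samples"} attribute.
#'
#' @param table counts-mode [AbundanceTable-class].
#' @param min_reads read-count threshold (default 10 reads).
#' @param min_fraction per-sample fraction threshold (default 1e-4, i.e.
#'   0.01\%).
#' @param rule \code{"and"} (conjunction, default) or \code{"or"}.
#' @param per \code{"cell"} (default) or \code{"taxon"}.
#' @return filtered counts-mode [AbundanceTable-class].
#' @examples
#' m <- matrix(c(9, 99991, 9, 49991), 2,
#'             dimnames = list(c("t1", "t2"), c("E1/A/L/1", "E1/B/L/1")))
#' f <- filterLowAbundance(AbundanceTable(m, mode = "counts"))
#' abundValues(f)["t1", ]   # 9/100000 zeroed, 9/50000 kept
#' @export
filterLowAbundance <- function(table, min_reads = 10, min_fraction = 1e-4,
                               rule = c("and", "or"),
                               per = c("cell", "taxon")) {
  stopifnot(is(table, "AbundanceTable"))
  if (abundMode(table) != "counts")
    stop("filterLowAbundance requires a counts-mode table")
  rule <- match.arg(rule)
  per <- match.arg(per)
  m <- abundValues(table)
  totals <- colSums(m)                       # pre-filter totals
  empty <- colnames(m)[totals == 0]
  nz <- totals > 0
  frac <- m
  frac[, nz] <- sweep(m[, nz, drop = FALSE], 2, totals[nz], "/")
  low_reads <- m < min_reads
  low_frac <- frac < min_fraction
  kill <- if (rule == "and") low_reads & low_frac else low_reads | low_frac
  kill[, !nz] <- FALSE                       # empty samples: test skipped
  if (per == "taxon") {
    # a taxon is removed everywhere when even its best cell fails the rule
    row_kill <- apply(kill | m == 0, 1L, all) & rowSums(m) > 0
    kill <- matrix(row_kill, nrow(m), ncol(m))
    kill[, !nz] <- FALSE
  }
  m[kill] <- 0
  keep <- rowSums(m) > 0
  out <- AbundanceTable(m[keep, , drop = FALSE],
                        sampleData = sampleInfo(table), mode = "counts")
  attr(out, "empty_samples") <- empty
  out
}

#' Convert counts to relative abundances
#'
#' Each sample column is divided by its read total; all-zero columns stay
#' all-zero and are reported via the \code{"empty_samples"} attribute.
#'
#' @param table counts-mode [AbundanceTable-class].
#' @return relative-mode [AbundanceTable-class].
#' @export
toRelative <- function(table) {
  stopifnot(is(table, "AbundanceTable"))
  if (abundMode(table) != "counts")
    stop("toRelative requires a counts-mode table")
  m <- abundValues(table)
  totals <- colSums(m)
  nz <- totals > 0
  m[, nz] <- sweep(m[, nz, drop = FALSE], 2, totals[nz], "/")
  out <- AbundanceTable(m, sampleData = sampleInfo(table), mode = "relative")
  attr(out, "empty_samples") <- colnames(m)[!nz]
  out
}

#' Aggregate taxa to species or genus level
#'
#' Rows sharing the same label at the requested level are summed; taxa with
#' no resolvable label keep their own row under
#' \code{"unassigned:<taxon id>"}. Column sums are conserved exactly.
#'
#' @param table an [AbundanceTable-class] (either mode).
#' @param taxonomy taxonomy map data.frame.
#' @param level \code{"species"} or \code{"genus"}.
#' @return aggregated [AbundanceTable-class].
#' @export
aggregateTaxa <- function(table, taxonomy, level = c("species", "genus")) {
  stopifnot(is(table, "AbundanceTable"))
  level <- match.arg(level)
  tax <- taxonomy[match(taxonIds(table), taxonomy$taxon_id), , drop = FALSE]
  lab <- tax[[level]]
  lab[is.na(lab) | lab == "" | lab == "unclassified"] <-
    paste0("unassigned:", taxonIds(table))[is.na(lab) | lab == "" |
                                             lab == "unclassified"]
  m <- abundValues(table)
  agg <- rowsum(m, group = lab, reorder = FALSE)
  AbundanceTable(agg, sampleData = sampleInfo(table), mode = abundMode(table))
}
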