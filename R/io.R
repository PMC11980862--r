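#' @importFrom utils read.delim write.table
NULL

# fixed dialect: UTF-8, TAB delimiter, "." decimal point
fmt_num <- function(x) {
  ifelse(x == round(x) & abs(x) < 2^53, format(x, scientific = FALSE,
                                               trim = TRUE),
         sprintf("%.17g", x))
}

#' Write an abundance table to TSV
#'
#' Taxa as rows, first column \code{taxon_id}, remaining columns keyed by
#' manifest keys. The storage mode is carried in a \code{#mode=} header
#' comment. Counts round-trip bit-exactly; fractions to better than 1e-12.
#'
#' @param table an [AbundanceTable-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeAbundanceTable <- function(table, path) {
  stopifnot(is(table, "AbundanceTable"))
  m <- abundValues(table)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c("#diatomRing abundance table",
               paste0("#mode=", abundMode(table)),
               paste(c("taxon_id", colnames(m)), collapse = "\t")), con)
  for (i in seq_len(nrow(m)))
    writeLines(paste(c(rownames(m)[i], fmt_num(m[i, ])), collapse = "\t"), con)
  invisible(path)
}

#' Read an abundance table from TSV
#'
#' @param path TSV file as written by [writeAbundanceTable()] (or any TSV
#'   with a \code{taxon_id} first column and manifest-key sample columns).
#' @param mode storage mode; taken from the \code{#mode=} header when
#'   present, else defaults to \code{"counts"}.
#' @param manifest optional manifest data.frame; sample columns not present
#'   in \code{manifest$key} are rejected.
#' @return an [AbundanceTable-class].
#' @export
readAbundanceTable <- function(path, mode = NULL, manifest = NULL) {
  header <- readLines(path, n = 10L, encoding = "UTF-8")
  mline <- grep("^#mode=", header, value = TRUE)
  if (is.null(mode))
    mode <- if (length(mline)) sub("^#mode=", "", mline[1L]) else "counts"
  df <- read.delim(path, comment.char = "#", check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 1L || names(df)[1L] != "taxon_id")
    stop("malformed header: first column must be 'taxon_id'")
  dup <- unique(df$taxon_id[duplicated(df$taxon_id)])
  if (length(dup))
    stop("duplicated taxon id(s): ", paste(dup, collapse = ", "))
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m))
    stop("non-numeric abundance values")
  storage.mode(m) <- "double"
  rownames(m) <- df$taxon_id
  neg <- which(m < 0, arr.ind = TRUE)
  if (nrow(neg))
    stop(sprintf("negative abundance at taxon '%s', sample '%s'",
                 rownames(m)[neg[1L, 1L]], colnames(m)[neg[1L, 2L]]))
  if (identical(mode, "relative")) {
    cs <- colSums(m)
    bad <- colnames(m)[cs > 0 & abs(cs - 1) > 1e-9]
    if (length(bad))
      stop("relative-mode column(s) not summing to 1: ",
           paste(bad, collapse = ", "))
  }
  sdata <- NULL
  if (!is.null(manifest)) {
    unknown <- setdiff(colnames(m), manifest$key)
    if (length(unknown))
      stop("sample column(s) not in manifest: ", paste(unknown, collapse = ", "))
    sdata <- manifest[match(colnames(m), manifest$key), , drop = FALSE]
  }
  AbundanceTable(m, sampleData = sdata, mode = mode)
}

#' Write / read a trait table (TSV)
#'
#' Columns: \code{taxon_id}, \code{s}, \code{v}, and optionally
#' \code{class_1 .. class_7} profile probabilities (rows summing to 1,
#' tolerance 1e-6).
#'
#' @param traits a [TraitTable-class].
#' @param path file path.
#' @return \code{path} invisibly (write); a [TraitTable-class] (read).
#' @export
writeTraitTable <- function(traits, path) {
  stopifnot(is(traits, "TraitTable"))
  df <- data.frame(taxon_id = traits@taxa, s = traits@s, v = traits@v,
                   stringsAsFactors = FALSE)
  if (nrow(traits@profiles) > 0L) {
    pr <- traits@profiles[traits@taxa, , drop = FALSE]
    colnames(pr) <- paste0("class_", seq_len(ncol(pr)))
    df <- cbind(df, as.data.frame(pr))
  }
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con)
  for (i in seq_len(nrow(df)))
    writeLines(paste(c(df$taxon_id[i], fmt_num(as.numeric(df[i, -1L]))),
                     collapse = "\t"), con)
  invisible(path)
}

#' @rdname writeTraitTable
#' @param classScores class scores for profile columns (default 1..7).
#' @export
readTraitTable <- function(path, classScores = 1:7) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("taxon_id", "s", "v")
  if (!all(need %in% names(df)))
    stop("trait table must have columns taxon_id, s, v")
  prof_cols <- grep("^class_", names(df), value = TRUE)
  profiles <- if (length(prof_cols)) {
    pm <- as.matrix(df[, prof_cols, drop = FALSE])
    rownames(pm) <- df$taxon_id
    pm
  } else matrix(numeric(), 0L, length(classScores))
  traitTable(df$taxon_id, df$s, df$v, profiles = profiles,
             classScores = classScores)
}

#' Read a taxonomy map (TSV)
#'
#' Columns \code{taxon_id}, \code{phylum}, \code{genus}, \code{species},
#' \code{label}; used by the filtering and aggregation steps.
#'
#' @param path TSV file path.
#' @return data.frame.
#' @export
readTaxonomyMap <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("taxon_id", "phylum", "genus", "species", "label")
  if (!all(need %in% names(df)))
    stop("taxonomy map must have columns: ", paste(need, collapse = ", "))
  df
}

#' Write / read a design specification (JSON)
#'
#' @param design a [DesignSpec-class].
#' @param path JSON file path.
#' @return \code{path} invisibly (write); a [DesignSpec-class] (read).
#' @export
writeDesign <- function(design, path) {
  stopifnot(is(design, "DesignSpec"))
  ex <- design@experiments
  recs <- lapply(seq_len(nrow(ex)), function(i)
    list(id = ex$id[[i]], material = ex$material[[i]],
         participants = ex$participants[[i]],
         replicates = ex$replicates[[i]],
         sample_types = ex$sample_types[[i]]))
  jsonlite::write_json(recs, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname writeDesign
#' @export
readDesign <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = TRUE,
                              simplifyDataFrame = FALSE)
  designSpec(recs)
}

#' Write / read a sample manifest (TSV)
#'
#' @param units manifest data.frame (see [expandDesign()]).
#' @param path TSV file path.
#' @return \code{path} invisibly (write); manifest data.frame (read).
#' @export
writeManifest <- function(units, path) {
  write.table(units, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname writeManifest
#' @export
readManifest <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  df$replicate <- as.integer(df$replicate)
  for (fl in intersect(c("sequenced", "false_positive_control",
                         "failed_amplicon"), names(df)))
    df[[fl]] <- as.logical(df[[fl]])
  df
}
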