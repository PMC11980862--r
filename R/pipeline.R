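#' Read a pipeline run configuration (YAML)
#'
#' Thresholds, paths, permutation counts and seeds for the orchestration
#' functions. Missing fields fall back to package defaults.
#'
#' @param path YAML file path.
#' @return a named list (class \code{"RunConfig"}).
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaultRunConfig(cfg)
}

#' @rdname readRunConfig
#' @param cfg partial configuration list to complete with defaults.
#' @export
defaultRunConfig <- function(cfg = list()) {
  def <- list(
    seed = 1L,
    output_dir = NULL,
    permutations = 999L,
    thresholds = list(min_reads = 10, min_fraction = 1e-4,
                      min_coverage = 0.7, youden_box = 3,
                      youden_line_tol = 2, swap_cutoff = 0.05,
                      mixture_cutoff = 0.05),
    paths = list()
  )
  cfg$thresholds <- utils::modifyList(def$thresholds,
                                      cfg$thresholds %||% list())
  out <- utils::modifyList(def, cfg)
  class(out) <- c("RunConfig", "list")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# provenance block embedded in every report: a hash of the scientific
# configuration (thresholds, seeds, sizes -- not output paths), the seed,
# and the package version
provenance <- function(config) {
  core <- list(seed = config$seed, permutations = config$permutations,
               thresholds = config$thresholds,
               experiment = config$experiment, depth = config$depth,
               n_taxa_R = config$n_taxa_R, n_taxa_L = config$n_taxa_L,
               shared_fraction = config$shared_fraction,
               random_sd = config$random_sd,
               biased_labs = config$biased_labs)
  list(config_hash = strHash(paste(deparse(core), collapse = "")),
       seed = config$seed,
       version = as.character(utils::packageVersion("diatomRing")))
}

# mean relative abundance per sample type over retained (non-control)
# samples: the consensus reference composition each unit is compared to
referenceProfiles <- function(rel_table,
                              sample_types = c("L", "R", "M")) {
  info <- sampleInfo(rel_table)
  m <- abundValues(rel_table)
  keep <- !isTRUE_vec(info$false_positive_control)
  profs <- list()
  for (st in sample_types) {
    cols <- info$key[keep & info$sample_type == st]
    if (!length(cols)) next
    p <- rowMeans(m[, cols, drop = FALSE])
    profs[[st]] <- p[p > 0] / sum(p)
  }
  profs
}

resolveInputs <- function(config) {
  tab <- config$table
  if (is.null(tab)) {
    manifest <- if (!is.null(config$paths$manifest))
      readManifest(config$paths$manifest) else NULL
    tab <- readAbundanceTable(config$paths$abundance, manifest = manifest)
  }
  traits <- config$traits
  if (is.null(traits)) {
    if (!is.null(config$paths$traits)) traits <- readTraitTable(config$paths$traits)
    else stop("config must supply 'traits' or paths$traits")
  }
  list(table = tab, traits = traits)
}

write_report <- function(bundle, config, stem) {
  if (is.null(config$output_dir)) return(invisible(NULL))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, name) {
    if (!is.null(df) && nrow(df))
      write.table(df, file.path(config$output_dir,
                                paste0(stem, "_", name, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
  }
  for (nm in names(bundle)) {
    if (is.data.frame(bundle[[nm]])) tsv(bundle[[nm]], nm)
  }
  jsonlite::write_json(
    bundle[!vapply(bundle, is.data.frame, TRUE)],
    file.path(config$output_dir, paste0(stem, "_report.json")),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE)
  invisible(NULL)
}

#' Run the proficiency-test analysis (E1/E2-style)
#'
#' Filters the counts table, computes per-sample diversity metrics and
#' cross-participant CVs, scores the trait-weighted indices, derives
#' per-sample-type z-scores and the Youden error classification on the
#' river/lake pair, issues the pass/fail verdict, scans sequenced blanks
#' for swapped or mixed compositions, and reports detection thresholds.
#'
#' @param config a [defaultRunConfig()]-style list; supply the data either
#'   in memory (\code{config$table}, an [AbundanceTable-class] in counts
#'   mode, and \code{config$traits}) or on disk (\code{config$paths}).
#'   \code{config$experiment} optionally restricts the analysis to one
#'   experiment id.
#' @return report bundle: \code{metrics}, \code{cv}, \code{ips},
#'   \code{ibd}, \code{zscores}, \code{youden}, \code{verdict},
#'   \code{anomalies}, \code{detection}, \code{provenance}. Written as
#'   TSV/JSON under \code{config$output_dir} when set.
#' @export
runProficiency <- function(config = defaultRunConfig()) {
  config <- defaultRunConfig(config)
  inp <- resolveInputs(config)
  th <- config$thresholds
  tab <- inp$table
  if (!is.null(config$experiment)) {
    info <- sampleInfo(tab)
    tab <- subsetSamples(tab, info$key[info$experiment %in% config$experiment])
  }
  filt <- filterLowAbundance(tab, min_reads = th$min_reads,
                             min_fraction = th$min_fraction)
  rel <- toRelative(filt)
  info <- sampleInfo(rel)
  retained <- !isTRUE_vec(info$false_positive_control)

  metrics <- metricTable(filt, prefix = "asv")
  cv <- metricCVSummary(metrics[retained & metrics$sample_type != "W", ,
                                drop = FALSE])

  ips <- indexScores(rel, inp$traits, "IPS", min_coverage = th$min_coverage)
  ibd <- indexScores(rel, inp$traits, "IBD", min_coverage = th$min_coverage)

  zrows <- list(); zvec <- list()
  for (st in intersect(c("R", "L"), unique(info$sample_type))) {
    sel <- retained & ips$sample_type == st & !is.na(ips$score)
    per_lab <- tapply(ips$score[sel], ips$participant[sel], mean)
    if (length(per_lab) >= 3L) {
      zs <- zScores(stats::setNames(as.numeric(per_lab), names(per_lab)))
      zs$sample_type <- st
      zs$degenerate <- attr(zs, "degenerate")
      zrows[[st]] <- zs
      zvec[[st]] <- stats::setNames(zs$z, zs$participant)
    }
  }
  zscores <- if (length(zrows)) do.call(rbind, zrows) else NULL
  youden <- if (all(c("R", "L") %in% names(zvec)))
    youdenClassify(zvec$R, zvec$L, box = th$youden_box,
                   line_tol = th$youden_line_tol) else NULL
  verdict <- if (!is.null(zscores)) proficiencyVerdict(zscores)
             else list(verdict = NA_character_, offenders = character())

  refs <- referenceProfiles(subsetSamples(rel, info$key[retained]))
  anomalies <- anomalyScan(rel, refs, swap_cutoff = th$swap_cutoff,
                           mixture_cutoff = th$mixture_cutoff)

  detection <- list()
  for (st in intersect(c("R", "L"), unique(info$sample_type))) {
    cols <- info$key[retained & info$sample_type == st]
    if (length(unique(info$participant[info$key %in% cols])) >= 2L)
      detection[[st]] <-
        detectionThreshold(subsetSamples(rel, cols))$threshold
  }

  bundle <- list(metrics = metrics, cv = cv, ips = ips, ibd = ibd,
                 zscores = zscores, youden = youden, verdict = verdict,
                 anomalies = anomalies, detection = detection,
                 provenance = provenance(config))
  write_report(bundle, config, "proficiency")
  bundle
}

#' Run the method-comparison analysis (E3/E4-style)
#'
#' Aggregates to species level when a taxonomy is supplied, then, per
#' environmental sample type: Bray-Curtis distances over all replicates,
#' nMDS ordination, PERMANOVA and MRPP on the participant factor,
#' per-replicate index scores, Kruskal-Wallis on IPS across participants,
#' and the IPS delta (max - min of participant medians).
#'
#' @param config as for [runProficiency()]; \code{config$taxonomy} (a
#'   taxonomy map data.frame) or \code{config$paths$taxonomy} enables
#'   species aggregation.
#' @return report bundle: \code{ips}, \code{ibd}, per-type \code{stats}
#'   (PERMANOVA/MRPP/Kruskal-Wallis/IPS delta/medians), \code{ordination},
#'   \code{provenance}.
#' @export
runComparison <- function(config = defaultRunConfig()) {
  config <- defaultRunConfig(config)
  inp <- resolveInputs(config)
  th <- config$thresholds
  tab <- inp$table
  if (!is.null(config$experiment)) {
    info <- sampleInfo(tab)
    tab <- subsetSamples(tab, info$key[info$experiment %in% config$experiment])
  }
  taxonomy <- config$taxonomy
  if (is.null(taxonomy) && !is.null(config$paths$taxonomy))
    taxonomy <- readTaxonomyMap(config$paths$taxonomy)
  filt <- filterLowAbundance(tab, min_reads = th$min_reads,
                             min_fraction = th$min_fraction)
  if (!is.null(taxonomy))
    filt <- aggregateTaxa(filt, taxonomy, "species")
  rel <- toRelative(filt)
  info <- sampleInfo(rel)
  retained <- !isTRUE_vec(info$false_positive_control)

  ips <- indexScores(rel, inp$traits, "IPS", min_coverage = th$min_coverage)
  ibd <- indexScores(rel, inp$traits, "IBD", min_coverage = th$min_coverage)

  stats_out <- list(); ords <- list()
  for (st in intersect(c("R", "L"), unique(info$sample_type))) {
    cols <- info$key[retained & info$sample_type == st]
    labs <- info$participant[match(cols, info$key)]
    if (length(unique(labs)) < 2L) next
    sub <- subsetSamples(rel, cols)
    d <- brayCurtisMatrix(sub)
    perma <- permanovaTest(d, labs, n_perm = config$permutations,
                           seed = config$seed)
    mrpp <- mrppTest(d, labs, n_perm = config$permutations,
                     seed = config$seed)
    ord <- nmdsOrdination(d, k = 2, seed = config$seed)
    sel <- ips$key %in% cols & !is.na(ips$score)
    med <- tapply(ips$score[sel], ips$participant[sel], stats::median)
    kw <- kruskalWallisTest(ips$score[sel], ips$participant[sel])
    stats_out[[st]] <- list(
      permanova = perma[c("statistic", "R2", "p", "n_perm")],
      mrpp = mrpp[c("statistic", "A", "p", "n_perm")],
      kruskal_wallis = kw,
      ips_median = as.list(med),
      ips_delta = max(med) - min(med),
      nmds_stress = ord$stress)
    ords[[st]] <- ord$points
  }
  bundle <- list(ips = ips, ibd = ibd, stats = stats_out,
                 ordination = ords, provenance = provenance(config))
  write_report(bundle, config, "comparison")
  bundle
}

#' Simulate a ring-trial dataset from a configuration
#'
#' Thin wrapper over the generator: builds (or loads) the design, reference
#' communities, lab effects and anomalies, simulates the counts table, and
#' writes table TSV, manifest TSV and ground-truth JSON when an output
#' directory is configured.
#'
#' @param config list with optional fields \code{design} (a
#'   [DesignSpec-class]; default [studyDesign()]), \code{depth},
#'   \code{n_taxa_R}, \code{n_taxa_L}, \code{shared_fraction},
#'   \code{random_sd}, \code{biased_labs} (named list participant ->
#'   log-scale magnitude of a trait-aligned bias), \code{anomalies} (list
#'   of [anomalySpec()] argument lists), \code{seed}, \code{output_dir}.
#' @return list: \code{table}, \code{truth}, \code{traits},
#'   \code{manifest}.
#' @export
simulateExperiment <- function(config = list()) {
  config <- defaultRunConfig(config)
  design <- config$design %||% studyDesign()
  profiles <- makeReferenceCommunities(
    n_taxa_R = config$n_taxa_R %||% 30L,
    n_taxa_L = config$n_taxa_L %||% 30L,
    shared_fraction = config$shared_fraction %||% 0.4,
    seed = config$seed)
  universe <- unique(unlist(lapply(profiles, names)))
  traits <- syntheticTraitTable(universe, seed = config$seed)
  participants <- unique(unlist(design@experiments$participants))
  random_sd <- config$random_sd %||% 0.05
  effects <- lapply(participants, function(p) {
    mag <- config$biased_labs[[p]]
    bias <- if (is.null(mag)) 0 else traitAlignedBias(traits, mag)
    labEffect(p, systematic_bias = bias, random_sd = random_sd,
              detection_floor = config$detection_floor %||% 0,
              dropout_prob = config$dropout_prob %||% 0)
  })
  names(effects) <- participants
  anomalies <- lapply(config$anomalies %||% list(), function(a)
    do.call(anomalySpec, a))
  truth <- syntheticTruth(profiles, effects, anomalies = anomalies,
                          depth = config$depth %||% 10000L,
                          seed = config$seed)
  sim <- simulateDataset(design, truth)
  manifest <- sampleInfo(sim$table)
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    writeAbundanceTable(sim$table,
                        file.path(config$output_dir, "abundance.tsv"))
    writeManifest(manifest, file.path(config$output_dir, "manifest.tsv"))
    writeTraitTable(traits, file.path(config$output_dir, "traits.tsv"))
    jsonlite::write_json(
      list(profiles = lapply(truth$profiles, as.list),
           depth = truth$depth, seed = truth$seed,
           anomalies = lapply(truth$anomalies, unclass),
           biased_labs = config$biased_labs %||% list(),
           provenance = provenance(config)),
      file.path(config$output_dir, "truth.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(table = sim$table, truth = truth, traits = traits,
       manifest = manifest)
}
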