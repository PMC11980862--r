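# deterministic 31-polynomial string hash on [0, 2^31-2]; used to derive
# per-unit RNG substreams so simulation is insertion-order independent
strHash <- function(x) {
  h <- 0
  for (c in utf8ToInt(x)) h <- (h * 31 + c) %% 2147483647
  h
}

unitSeed <- function(master_seed, key) {
  (strHash(paste0(master_seed, ":", key))) %% 2147483647
}

#' Generate reference community profiles
#'
#' Builds the calibrated communities the ring trial circulates: a river
#' community \code{R}, a lake community \code{L} sharing a fraction of taxa
#' with \code{R}, a 12-taxon mock community \code{M}, and the empty water
#' blank \code{W}. Relative abundances follow a geometric rank series
#' (evenness parameter \code{k}: the i-th ranked taxon has abundance
#' proportional to \code{k^(i-1)}) or a lognormal model; either creates the
#' abundant/rare split that detection-threshold analysis needs.
#'
#' @param n_taxa_R,n_taxa_L number of taxa in the river / lake community.
#' @param shared_fraction fraction (of the smaller community) of taxa shared
#'   between R and L.
#' @param abundance_model \code{"geometric"} or \code{"lognormal"}.
#' @param evenness geometric ratio k in (0, 1); ignored for lognormal.
#' @param sdlog lognormal sd; ignored for geometric.
#' @param seed integer seed.
#' @return named list of profiles \code{R}, \code{L}, \code{M}, \code{W};
#'   each a named numeric vector of fractions summing to 1 (\code{W} is
#'   empty).
#' @examples
#' prof <- makeReferenceCommunities(seed = 7)
#' length(prof$M)   # 12 mock strains
#' sum(prof$R)      # 1
#' @export
makeReferenceCommunities <- function(n_taxa_R = 30L, n_taxa_L = 30L,
                                     shared_fraction = 0.4,
                                     abundance_model = c("geometric",
                                                         "lognormal"),
                                     evenness = 0.8, sdlog = 1, seed = 1L) {
  abundance_model <- match.arg(abundance_model)
  stopifnot(n_taxa_R >= 1L, n_taxa_L >= 1L,
            shared_fraction >= 0, shared_fraction <= 1)
  set.seed(as.integer(seed))
  n_shared <- floor(shared_fraction * min(n_taxa_R, n_taxa_L))
  shared <- sprintf("SHA%02d", seq_len(n_shared))
  r_only <- sprintf("RIV%02d", seq_len(n_taxa_R - n_shared))
  l_only <- sprintf("LAK%02d", seq_len(n_taxa_L - n_shared))
  mock <- sprintf("MOCK%02d", 1:12)

  ranked <- function(n) {
    p <- switch(abundance_model,
                geometric = evenness^(seq_len(n) - 1),
                lognormal = sort(stats::rlnorm(n, 0, sdlog),
                                 decreasing = TRUE))
    p / sum(p)
  }
  assign_profile <- function(taxa) {
    p <- ranked(length(taxa))
    names(p) <- sample(taxa)       # random rank-to-taxon assignment
    p[taxa]
  }
  list(R = assign_profile(c(shared, r_only)),
       L = assign_profile(c(shared, l_only)),
       M = assign_profile(mock),
       W = stats::setNames(numeric(0), character(0)))
}

#' Per-laboratory effect parameters
#'
#' A lab's systematic bias is a per-taxon multiplicative factor on the log
#' scale (extraction/PCR taxon-efficiency bias); replicate noise is an iid
#' lognormal perturbation; taxa whose biased relative abundance falls below
#' the detection floor drop out with the stated probability.
#'
#' @param participant lab code.
#' @param systematic_bias named per-taxon log-scale bias vector (taxa not
#'   named get 0), or a single 0 for an unbiased lab.
#' @param random_sd log-scale replicate noise sd (>= 0).
#' @param detection_floor relative abundance below which dropout can occur.
#' @param dropout_prob probability a below-floor taxon drops out.
#' @return object of class \code{"LabEffect"} (a validated list).
#' @export
labEffect <- function(participant, systematic_bias = 0, random_sd = 0.05,
                      detection_floor = 0, dropout_prob = 0) {
  stopifnot(random_sd >= 0, detection_floor >= 0, detection_floor < 1,
            dropout_prob >= 0, dropout_prob <= 1)
  structure(list(participant = participant,
                 systematic_bias = systematic_bias,
                 random_sd = random_sd,
                 detection_floor = detection_floor,
                 dropout_prob = dropout_prob),
            class = "LabEffect")
}

#' Trait-aligned systematic bias vector
#'
#' A bias that shifts trait-weighted composition: taxa with sensitivity
#' \code{s >= 4} are over-amplified by \code{+magnitude} (log scale) and
#' taxa with \code{s <= 2} under-amplified by \code{-magnitude}. Used to
#' inject a detectable protocol-level fault into one lab.
#'
#' @param traits a [TraitTable-class].
#' @param magnitude log-scale bias magnitude.
#' @return named numeric bias vector over the trait table's taxa.
#' @export
traitAlignedBias <- function(traits, magnitude = 1.5) {
  s <- traitS(traits)
  b <- numeric(length(s))
  b[s >= 4] <- magnitude
  b[s <= 2] <- -magnitude
  stats::setNames(b, names(s))
}

#' Specify an injected anomaly
#'
#' @param target manifest key of the affected unit.
#' @param kind \code{"swap"} (unit receives another community wholesale),
#'   \code{"mixture"} (unit receives \code{alpha * A + (1 - alpha) * B}) or
#'   \code{"contamination"} (a fraction \code{alpha} of a source community
#'   mixed into the unit's own).
#' @param sources community id(s): one for swap/contamination, two for
#'   mixture.
#' @param alpha mixing fraction in [0, 1]; must be strictly inside (0, 1)
#'   for mixtures.
#' @return object of class \code{"AnomalySpec"}.
#' @export
anomalySpec <- function(target, kind = c("swap", "mixture", "contamination"),
                        sources, alpha = 0.5) {
  kind <- match.arg(kind)
  if (kind == "mixture" && (length(sources) != 2L || alpha <= 0 || alpha >= 1))
    stop("mixture anomalies need 2 sources and alpha in (0,1)")
  if (kind %in% c("swap", "contamination") && length(sources) != 1L)
    stop(kind, " anomalies need exactly 1 source")
  stopifnot(alpha >= 0, alpha <= 1)
  structure(list(target = target, kind = kind, sources = sources,
                 alpha = alpha), class = "AnomalySpec")
}

#' Assemble generator ground truth
#'
#' @param profiles community profiles from [makeReferenceCommunities()].
#' @param lab_effects named list of [labEffect()] records, one per
#'   participant in the design.
#' @param anomalies list of [anomalySpec()] records.
#' @param depth sequencing depth (reads per sample); a single number or a
#'   vector named by manifest key.
#' @param seed master seed; per-unit substreams are derived by hashing the
#'   unit key, so results do not depend on unit order.
#' @return object of class \code{"SyntheticTruth"}.
#' @export
syntheticTruth <- function(profiles, lab_effects, anomalies = list(),
                           depth = 10000L, seed = 1L) {
  stopifnot(all(c("R", "L", "M", "W") %in% names(profiles)))
  structure(list(profiles = profiles, lab_effects = lab_effects,
                 anomalies = anomalies, depth = depth,
                 seed = as.integer(seed)),
            class = "SyntheticTruth")
}

# expected (pre-sampling) composition of a unit on the full taxon universe
expectedComposition <- function(truth, universe, sample_type, key) {
  anom <- NULL
  for (a in truth$anomalies) if (identical(a$target, key)) anom <- a
  p <- stats::setNames(numeric(length(universe)), universe)
  base <- truth$profiles[[sample_type]]
  p[names(base)] <- base
  if (!is.null(anom)) {
    src <- lapply(anom$sources, function(s) {
      v <- stats::setNames(numeric(length(universe)), universe)
      v[names(truth$profiles[[s]])] <- truth$profiles[[s]]
      v
    })
    p <- switch(anom$kind,
                swap = src[[1L]],
                mixture = anom$alpha * src[[1L]] + (1 - anom$alpha) * src[[2L]],
                contamination = {
                  mixed <- (1 - anom$alpha) * p + anom$alpha * src[[1L]]
                  if (sum(p) == 0) src[[1L]] else mixed / sum(mixed)
                })
  }
  p
}

#' Simulate a multi-laboratory metabarcoding dataset
#'
#' For each sequenced unit the expected composition is the unit's community
#' profile (after any injected anomaly), perturbed per taxon by the lab's
#' systematic bias and replicate noise on the log scale
#' (\code{p' proportional to p * exp(bias + eps)}), thinned by dropout below
#' the detection floor, renormalised, and sampled as
#' \code{multinomial(depth, p')}. Blanks yield all-zero columns unless an
#' anomaly overwrites them. Column read sums equal the configured depth
#' exactly (zero for blanks).
#'
#' @param design a [DesignSpec-class].
#' @param truth a [syntheticTruth()] record covering every participant.
#' @param units optional pre-built manifest; when omitted the design is
#'   expanded and sequencing rules applied with W exceptions for every W
#'   unit targeted by an anomaly.
#' @return list with \code{table} (an [AbundanceTable-class] in counts
#'   mode over the sequenced units) and \code{truth}.
#' @examples
#' prof <- makeReferenceCommunities(seed = 3)
#' d <- designSpec(list(list(id = "E1", material = "biofilm",
#'                           participants = c("A", "B"), replicates = 1,
#'                           sample_types = c("L", "R"))))
#' eff <- list(A = labEffect("A"), B = labEffect("B"))
#' sim <- simulateDataset(d, syntheticTruth(prof, eff, depth = 1000, seed = 9))
#' colSums(abundValues(sim$table))   # all exactly 1000
#' @export
simulateDataset <- function(design, truth, units = NULL) {
  stopifnot(is(design, "DesignSpec"), inherits(truth, "SyntheticTruth"))
  if (is.null(units)) {
    units <- expandDesign(design)
    w_exc <- intersect(vapply(truth$anomalies, `[[`, "", "target"),
                       units$key[units$sample_type == "W"])
    units <- applySequencingRules(units, w_exceptions = w_exc)
  }
  participants <- unique(units$participant)
  missing <- setdiff(participants, names(truth$lab_effects))
  if (length(missing))
    stop("no lab effect for participant(s): ", paste(missing, collapse = ", "))

  seq_units <- units[units$sequenced, , drop = FALSE]
  universe <- unique(unlist(lapply(truth$profiles, names)))
  counts <- matrix(0, length(universe), nrow(seq_units),
                   dimnames = list(universe, seq_units$key))
  for (j in seq_len(nrow(seq_units))) {
    key <- seq_units$key[j]
    p <- expectedComposition(truth, universe, seq_units$sample_type[j], key)
    if (sum(p) == 0) next                      # blank: stays all-zero
    eff <- truth$lab_effects[[seq_units$participant[j]]]
    set.seed(unitSeed(truth$seed, key))
    bias <- stats::setNames(numeric(length(universe)), universe)
    if (length(eff$systematic_bias) > 1L || any(eff$systematic_bias != 0)) {
      bn <- intersect(names(eff$systematic_bias), universe)
      bias[bn] <- eff$systematic_bias[bn]
    }
    eps <- stats::rnorm(length(universe), 0, eff$random_sd)
    pp <- p * exp(bias + eps)
    pp <- pp / sum(pp)
    if (eff$dropout_prob > 0 && eff$detection_floor > 0) {
      below <- pp > 0 & pp < eff$detection_floor
      drop <- below & stats::runif(length(pp)) < eff$dropout_prob
      pp[drop] <- 0
      pp <- pp / sum(pp)
    }
    depth <- if (length(truth$depth) > 1L) truth$depth[[key]] else truth$depth
    counts[, j] <- stats::rmultinom(1L, size = depth, prob = pp)[, 1L]
  }
  tab <- AbundanceTable(counts, sampleData = seq_units, mode = "counts")
  list(table = tab, truth = truth)
}
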