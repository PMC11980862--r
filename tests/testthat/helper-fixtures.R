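# Shared fixture builders; everything is generated in code.

# a small counts table with parseable manifest keys
toyCounts <- function(values = NULL, taxa = NULL, keys = NULL) {
  if (is.null(values)) {
    values <- matrix(c(30, 70, 0,
                       10, 80, 10,
                       50, 40, 10,
                       25, 25, 50), nrow = 3,
                     dimnames = list(
                       c("t1", "t2", "t3"),
                       c("E1/A/L/1", "E1/B/L/1", "E1/C/L/1", "E1/D/L/1")))
  } else {
    dimnames(values) <- list(taxa, keys)
  }
  AbundanceTable(values, mode = "counts")
}

toyTaxonomy <- function(taxa, phylum = "Bacillariophyta",
                        species = NULL, genus = NULL) {
  data.frame(taxon_id = taxa,
             phylum = rep_len(phylum, length(taxa)),
             genus = if (is.null(genus)) paste0("g_", taxa) else genus,
             species = if (is.null(species)) paste0("sp_", taxa) else species,
             label = rep_len(phylum, length(taxa)),
             stringsAsFactors = FALSE)
}

# identity taxonomy: every taxon its own species label equal to the taxon
# id, so aggregation leaves tables (and trait joins) unchanged
identityTaxonomy <- function(taxa)
  toyTaxonomy(taxa, species = taxa, genus = taxa)

# random relative-abundance vector over n taxa
randomProfile <- function(n, seed) {
  set.seed(seed)
  p <- stats::rexp(n)
  stats::setNames(p / sum(p), sprintf("t%02d", seq_len(n)))
}

# small multi-participant relative table for one sample type
multiLabTable <- function(n_labs = 4, n_taxa = 6, seed = 1,
                          sample_type = "L", experiment = "E1") {
  set.seed(seed)
  m <- matrix(stats::rexp(n_labs * n_taxa), n_taxa, n_labs)
  m <- sweep(m, 2, colSums(m), "/")
  dimnames(m) <- list(sprintf("t%02d", seq_len(n_taxa)),
                      unitKey(experiment, LETTERS[seq_len(n_labs)],
                              sample_type, 1))
  AbundanceTable(m, mode = "relative")
}

# a simulated two-archetype comparison dataset: labs in group 1 unbiased,
# labs in group 2 share a common bias vector -> participant/archetype effect
archetypeSimulation <- function(seed, n_labs = 6, reps = 3, depth = 5000,
                                bias_mag = 1.0) {
  prof <- makeReferenceCommunities(seed = seed)
  labs <- LETTERS[seq_len(n_labs)]
  design <- designSpec(list(list(id = "E3", material = "biofilm",
                                 participants = labs, replicates = reps,
                                 sample_types = c("L", "R"))))
  universe <- unique(unlist(lapply(prof, names)))
  set.seed(seed)
  arch_bias <- stats::setNames(stats::rnorm(length(universe), 0, bias_mag),
                               universe)
  eff <- lapply(seq_along(labs), function(i) {
    b <- if (i > n_labs / 2) arch_bias else 0
    labEffect(labs[i], systematic_bias = b, random_sd = 0.05)
  })
  names(eff) <- labs
  truth <- syntheticTruth(prof, eff, depth = depth, seed = seed)
  simulateDataset(design, truth)
}
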