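#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' \code{1 - 2 * sum(min(x, y)) / (sum(x) + sum(y))}: 0 for identical
#' vectors, 1 for disjoint supports. Symmetric and zero only for equal
#' vectors, but not a metric (no triangle inequality).
#'
#' @param x,y non-negative vectors on a shared taxon universe (same order).
#' @return dissimilarity in [0, 1]; \code{NA} with attribute
#'   \code{undefined = TRUE} when both vectors are all-zero.
#' @examples
#' brayCurtis(c(0.7, 0.3, 0), c(0.3, 0.3, 0.4))  # 0.4
#' @export
brayCurtis <- function(x, y) {
  stopifnot(length(x) == length(y), all(x >= 0), all(y >= 0))
  tot <- sum(x) + sum(y)
  if (tot == 0) {
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    return(out)
  }
  1 - 2 * sum(pmin(x, y)) / tot
}

#' Bray-Curtis distance matrix for an abundance table
#'
#' @param table relative-mode [AbundanceTable-class] (samples as columns).
#' @return a \code{dist} object over the samples.
#' @export
brayCurtisMatrix <- function(table) {
  stopifnot(is(table, "AbundanceTable"))
  if (abundMode(table) != "relative")
    stop("brayCurtisMatrix expects a relative-mode table")
  vegan::vegdist(t(abundValues(table)), method = "bray")
}

# all n! permutations of 1..n (n small), one per row
allPermutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- allPermutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

# permutation engine shared by PERMANOVA and MRPP: exhaustive when n! fits
# the budget, seeded Monte-Carlo otherwise
permutationSet <- function(n, n_perm, seed, exhaustive_max = 10000) {
  n_total <- factorial(n)
  if (n_total <= exhaustive_max) {
    list(perms = allPermutations(n), exhaustive = TRUE)
  } else {
    if (!is.null(seed)) set.seed(as.integer(seed))
    list(perms = t(vapply(seq_len(n_perm), function(i) sample.int(n),
                          integer(n))),
         exhaustive = FALSE)
  }
}

permanova_stats <- function(D2, groups) {
  n <- nrow(D2)
  a <- length(unique(groups))
  ss_total <- sum(D2[upper.tri(D2)]) / n
  ss_within <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (length(idx) > 1L) {
      sub <- D2[idx, idx, drop = FALSE]
      ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(idx)
    }
  }
  ss_between <- ss_total - ss_within
  f <- (ss_between / (a - 1)) / (ss_within / (n - a))
  list(F = f, R2 = ss_between / ss_total, ss_total = ss_total,
       ss_within = ss_within)
}

#' One-factor PERMANOVA on a distance matrix
#'
#' Anderson-style partition of the total sum of squared distances into
#' between- and within-group components; pseudo-F and R2 =
#' SS_between / SS_total, with a permutation p-value
#' \code{(1 + #\{F_perm >= F_obs\}) / (1 + n_perm)} under random label
#' permutations. When the total number of label permutations is at most
#' 10,000 (n <= 7) the full permutation set is enumerated instead and the
#' p-value is exact.
#'
#' @param dist a \code{dist} or symmetric matrix of dissimilarities.
#' @param groups factor-like group labels, one per sample.
#' @param n_perm Monte-Carlo permutation count (default 9999).
#' @param seed seed for the Monte-Carlo draw.
#' @return list: \code{statistic} (pseudo-F), \code{R2}, \code{p},
#'   \code{n_perm}, \code{exhaustive}, \code{seed}, \code{flag}.
#' @export
permanovaTest <- function(dist, groups, n_perm = 9999, seed = NULL) {
  D <- as.matrix(dist)
  groups <- as.character(groups)
  stopifnot(nrow(D) == length(groups))
  if (length(unique(groups)) < 2L)
    stop("PERMANOVA needs at least 2 groups")
  D2 <- D^2
  obs <- permanova_stats(D2, groups)
  if (obs$ss_total == 0 || is.nan(obs$F))
    return(list(statistic = obs$F, R2 = obs$R2, p = NA_real_,
                n_perm = 0L, exhaustive = FALSE, seed = seed,
                flag = "degenerate_distances"))
  ps <- permutationSet(length(groups), n_perm, seed)
  f_perm <- apply(ps$perms, 1L, function(ix)
    permanova_stats(D2, groups[ix])$F)
  f_perm[!is.finite(f_perm)] <- Inf     # all-between degenerate permutations
  p <- if (ps$exhaustive)
    mean(f_perm >= obs$F - 1e-12)
  else
    (1 + sum(f_perm >= obs$F - 1e-12)) / (1 + nrow(ps$perms))
  list(statistic = obs$F, R2 = obs$R2, p = p, n_perm = nrow(ps$perms),
       exhaustive = ps$exhaustive, seed = seed, flag = NA_character_)
}

mrpp_delta <- function(D, groups, valid_groups) {
  num <- 0; den <- 0
  for (g in valid_groups) {
    idx <- which(groups == g)
    sub <- D[idx, idx, drop = FALSE]
    num <- num + length(idx) * mean(sub[upper.tri(sub)])
    den <- den + length(idx)
  }
  num / den
}

#' Multi-response permutation procedure (MRPP)
#'
#' Observed delta is the group-size-weighted mean within-group
#' dissimilarity; the chance-corrected effect size is
#' \code{A = 1 - delta / E[delta]} with \code{E[delta]} the permutation
#' expectation (the overall mean dissimilarity). The p-value counts
#' permuted deltas at or below the observed one, with the same exhaustive /
#' Monte-Carlo switch as [permanovaTest()]. Singleton groups contribute no
#' within-group distance and are excluded, with a report in \code{flag}.
#'
#' @inheritParams permanovaTest
#' @return list: \code{statistic} (delta), \code{A}, \code{p},
#'   \code{n_perm}, \code{exhaustive}, \code{seed}, \code{flag}.
#' @export
mrppTest <- function(dist, groups, n_perm = 9999, seed = NULL) {
  D <- as.matrix(dist)
  groups <- as.character(groups)
  stopifnot(nrow(D) == length(groups))
  sizes <- table(groups)
  if (length(sizes) < 2L)
    stop("MRPP needs at least 2 groups")
  valid <- names(sizes)[sizes > 1L]
  flag <- if (length(valid) < length(sizes))
    paste0("singleton group(s) excluded: ",
           paste(setdiff(names(sizes), valid), collapse = ", "))
  else NA_character_
  if (!length(valid))
    stop("MRPP needs at least one group with 2+ members")
  obs <- mrpp_delta(D, groups, valid)
  e_delta <- mean(D[upper.tri(D)])
  ps <- permutationSet(length(groups), n_perm, seed)
  d_perm <- apply(ps$perms, 1L, function(ix) mrpp_delta(D, groups[ix], valid))
  p <- if (ps$exhaustive)
    mean(d_perm <= obs + 1e-12)
  else
    (1 + sum(d_perm <= obs + 1e-12)) / (1 + nrow(ps$perms))
  list(statistic = obs, A = 1 - obs / e_delta, p = p,
       n_perm = nrow(ps$perms), exhaustive = ps$exhaustive, seed = seed,
       flag = flag)
}

#' Non-metric multidimensional scaling of a distance matrix
#'
#' Kruskal stress-1 nMDS via \code{vegan::metaMDS} (monoMDS engine,
#' iterative monotone regression) with seeded random restarts. Coordinates
#' are centred and rotated to principal axes, with axis signs fixed so the
#' largest-magnitude score on each axis is positive, making the embedding
#' deterministic given the seed.
#'
#' @param dist a \code{dist} or symmetric dissimilarity matrix.
#' @param k embedding dimension (default 2).
#' @param restarts random restarts (best solution kept).
#' @param seed integer seed.
#' @return list: \code{points} (n x k matrix), \code{stress} (Kruskal
#'   stress-1), \code{converged} flag.
#' @export
nmdsOrdination <- function(dist, k = 2, restarts = 20, seed = 1L) {
  d <- stats::as.dist(dist)
  stopifnot(attr(d, "Size") >= k + 1)
  set.seed(as.integer(seed))
  fit <- suppressWarnings(suppressMessages(
    vegan::metaMDS(d, k = k, trymax = restarts, trace = 0,
                   autotransform = FALSE, wascores = FALSE)))
  pts <- fit$points
  pts <- scale(pts, center = TRUE, scale = FALSE)
  for (j in seq_len(ncol(pts)))
    if (pts[which.max(abs(pts[, j])), j] < 0) pts[, j] <- -pts[, j]
  list(points = pts, stress = fit$stress, converged = fit$converged > 0)
}

#' Kruskal-Wallis rank test on index scores
#'
#' Tie-corrected H with the chi-squared approximation on
#' \code{groups - 1} degrees of freedom (via \code{stats::kruskal.test});
#' the all-identical degenerate case is defined as H = 0, p = 1.
#'
#' @param values numeric scores.
#' @param groups group labels, one per score.
#' @return list: \code{H}, \code{p}, \code{df}.
#' @export
kruskalWallisTest <- function(values, groups) {
  groups <- as.character(groups)
  stopifnot(length(values) == length(groups), length(values) >= 2L)
  if (length(unique(groups)) < 2L)
    stop("Kruskal-Wallis needs at least 2 groups")
  if (length(unique(values)) == 1L)
    return(list(H = 0, p = 1, df = length(unique(groups)) - 1L))
  kt <- stats::kruskal.test(values, factor(groups))
  list(H = unname(kt$statistic), p = kt$p.value, df = unname(kt$parameter))
}
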