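#' Proficiency z-scores
#'
#' Standardised scores \code{z = (x - mu) / sigma} where \code{mu} and
#' \code{sigma} are the plain mean and sample SD over all participants
#' (the scored participant included). Zones follow the ring-trial
#' convention: \code{|z| <= 2} in control, \code{2 < |z| <= 3} warning,
#' \code{|z| > 3} action. When every participant returns the same score
#' (\code{sigma = 0}) all z are defined as 0 and the result is flagged
#' \code{degenerate_dispersion} — a structurally successful test. A
#' robust variant (median / MAD) is available behind \code{robust = TRUE}.
#'
#' @param index_values named numeric vector, one index score per
#'   participant.
#' @param robust use median and MAD instead of mean and sample SD.
#' @return data.frame with columns \code{participant}, \code{x}, \code{mu},
#'   \code{sigma}, \code{z}, \code{zone}; attribute \code{degenerate} TRUE
#'   when sigma was 0.
#' @examples
#' z <- zScores(c(A = 15.9, B = 16.1, C = 16.0, D = 15.8))
#' z$zone
#' @export
zScores <- function(index_values, robust = FALSE) {
  if (length(index_values) < 3L)
    stop("z-scores need at least 3 participants")
  x <- as.numeric(index_values)
  mu <- if (robust) stats::median(x) else mean(x)
  sigma <- if (robust) stats::mad(x) else stats::sd(x)
  degenerate <- sigma == 0
  z <- if (degenerate) rep(0, length(x)) else (x - mu) / sigma
  zone <- ifelse(abs(z) > 3, "action",
                 ifelse(abs(z) > 2, "warning", "in_control"))
  out <- data.frame(participant = names(index_values), x = x, mu = mu,
                    sigma = sigma, z = z, zone = zone,
                    stringsAsFactors = FALSE)
  attr(out, "degenerate") <- degenerate
  out
}

#' Proficiency-test verdict
#'
#' The test fails when any participant's \code{|z| > 3}; offenders are
#' listed.
#'
#' @param zresults data.frame from [zScores()] (or several, row-bound).
#' @return list with \code{verdict} (\code{"pass"}/\code{"fail"}) and
#'   \code{offenders} (character).
#' @export
proficiencyVerdict <- function(zresults) {
  if (is.null(zresults) || nrow(zresults) == 0L)
    stop("empty z-score input")
  off <- unique(zresults$participant[abs(zresults$z) > 3])
  list(verdict = if (length(off)) "fail" else "pass", offenders = off)
}

#' Youden error classification of paired z-scores
#'
#' Each participant's pair (z on the river item, z on the lake item) is
#' rotated 45 degrees into a systematic component \code{u = (z_R + z_L) /
#' sqrt(2)} (along the reference line) and a random component \code{v =
#' (z_R - z_L) / sqrt(2)} (distance from it). Outside the \code{box}-SD
#' square: near the line (\code{|v| <= line_tol}) is a systematic error,
#' far from it a total error. Inside the box, \code{|v| > line_tol} marks
#' a random error; otherwise the lab is in control. A 95\% circle radius
#' \code{sqrt(qchisq(0.95, 2))} on the standardised axes is attached for
#' plotting.
#'
#' @param z_river,z_lake named numeric z-score vectors (names =
#'   participants); participants missing from either side are skipped and
#'   reported via the \code{"skipped"} attribute.
#' @param box half-width of the control box in SD units (default 3).
#' @param line_tol tolerance band around the 45-degree line, in SD units
#'   on the rotated axis (default 2, mirroring the 2-SD warning
#'   convention).
#' @return data.frame with \code{participant}, \code{z_river},
#'   \code{z_lake}, \code{u}, \code{v}, \code{label}; attributes
#'   \code{circle_radius} and \code{skipped}.
#' @examples
#' youdenClassify(c(A = 3.5, B = 1), c(A = 3.4, B = 1))$label
#' @export
youdenClassify <- function(z_river, z_lake, box = 3, line_tol = 2) {
  common <- intersect(names(z_river), names(z_lake))
  skipped <- setdiff(union(names(z_river), names(z_lake)), common)
  zr <- as.numeric(z_river[common])
  zl <- as.numeric(z_lake[common])
  u <- (zr + zl) / sqrt(2)
  v <- (zr - zl) / sqrt(2)
  outside <- abs(zr) > box | abs(zl) > box
  label <- ifelse(outside,
                  ifelse(abs(v) <= line_tol, "systematic_error", "total_error"),
                  ifelse(abs(v) > line_tol, "random_error", "in_control"))
  out <- data.frame(participant = common, z_river = zr, z_lake = zl,
                    u = u, v = v, label = label, stringsAsFactors = FALSE)
  attr(out, "circle_radius") <- sqrt(stats::qchisq(0.95, 2))
  attr(out, "skipped") <- skipped
  out
}

#' Taxon detection threshold across participants
#'
#' For every taxon of a sample type, the representative abundance is its
#' maximum (or mean) relative abundance over the participants that detect
#' it. The detection threshold is the largest representative abundance
#' among taxa missed by at least one participant; every taxon whose
#' representative abundance lies strictly above it was detected by all
#' participants. 0 when no taxon is missed.
#'
#' @param table relative-mode [AbundanceTable-class]; columns are one
#'   sample per participant (replicates of a participant may be present
#'   and are pooled by maximum).
#' @param representative \code{"max"} (default) or \code{"mean"} over
#'   detecting participants.
#' @return list with \code{threshold} (fraction), \code{per_taxon}
#'   data.frame (\code{taxon}, \code{representative}, \code{n_detecting},
#'   \code{missed}).
#' @export
detectionThreshold <- function(table, representative = c("max", "mean")) {
  stopifnot(is(table, "AbundanceTable"))
  representative <- match.arg(representative)
  if (abundMode(table) != "relative")
    stop("detectionThreshold requires a relative-mode table")
  info <- sampleInfo(table)
  if (length(unique(info$participant)) < 2L)
    stop("detectionThreshold needs >= 2 participants")
  m <- abundValues(table)
  labs <- unique(info$participant)
  # participant-level detection: max over that participant's columns
  per_lab <- vapply(labs, function(lb)
    apply(m[, info$participant == lb, drop = FALSE], 1L, max), numeric(nrow(m)))
  detected <- per_lab > 0
  present <- rowSums(detected) > 0
  rep_ab <- vapply(seq_len(nrow(m)), function(i) {
    d <- per_lab[i, detected[i, ]]
    if (!length(d)) 0 else if (representative == "max") max(d) else mean(d)
  }, 0)
  missed <- present & rowSums(!detected) > 0
  thr <- if (any(missed)) max(rep_ab[missed]) else 0
  list(threshold = thr,
       per_taxon = data.frame(taxon = rownames(m), representative = rep_ab,
                              n_detecting = rowSums(detected),
                              missed = missed, stringsAsFactors = FALSE))
}

# align two or more named profiles on the union of their taxa
alignProfiles <- function(...) {
  profs <- list(...)
  universe <- unique(unlist(lapply(profs, names)))
  lapply(profs, function(p) {
    v <- stats::setNames(numeric(length(universe)), universe)
    v[names(p)] <- p
    v
  })
}

#' Match a sample composition to reference communities
#'
#' Bray-Curtis dissimilarity between the query and each reference profile
#' (aligned on the union of taxa); the best match is the minimiser, ties
#' broken by reference name order.
#'
#' @param query named relative-abundance vector.
#' @param references named list of reference profiles.
#' @return list with \code{best}, \code{dissimilarity}, and the full
#'   \code{dissimilarities} vector; \code{best = NA} with flag
#'   \code{"empty_query"} for an all-zero query.
#' @examples
#' prof <- makeReferenceCommunities(seed = 2)
#' matchComposition(prof$L, prof[c("L", "R", "M")])$best  # "L"
#' @export
matchComposition <- function(query, references) {
  stopifnot(length(references) > 0L)
  if (sum(query) == 0)
    return(list(best = NA_character_, dissimilarity = NA_real_,
                dissimilarities = NULL, flag = "empty_query"))
  nm <- sort(names(references))
  d <- vapply(nm, function(r) {
    al <- alignProfiles(query, references[[r]])
    brayCurtis(al[[1L]], al[[2L]])
  }, 0)
  best <- nm[which.min(d)]       # which.min takes the first = name order
  list(best = best, dissimilarity = unname(d[best]), dissimilarities = d,
       flag = NA_character_)
}

#' Fit a two-community mixture to a query composition
#'
#' Finds \code{alpha} minimising \code{|| query - (alpha A + (1 - alpha) B)
#' ||_2} in closed form (projection of \code{query - B} on \code{A - B}),
#' clipped to [0, 1]. The residual is the Bray-Curtis dissimilarity between
#' the query and the fitted mixture; the unit is flagged
#' \code{mixture_suspect} when the residual is below \code{cutoff} and
#' \code{alpha} lies in [0.2, 0.8].
#'
#' @param query named relative-abundance vector.
#' @param ref_A,ref_B named reference profiles.
#' @param cutoff residual cutoff for the mixture verdict (default 0.05).
#' @return list with \code{alpha}, \code{residual}, \code{verdict}
#'   (\code{"mixture_suspect"} or \code{"clean"}); \code{alpha = NA} with
#'   flag when the references coincide.
#' @examples
#' prof <- makeReferenceCommunities(seed = 2)
#' fitMixture(prof$L, prof$L, prof$M)$alpha   # 1: the query is pure L
#' @export
fitMixture <- function(query, ref_A, ref_B, cutoff = 0.05) {
  al <- alignProfiles(query, ref_A, ref_B)
  q <- al[[1L]]; A <- al[[2L]]; B <- al[[3L]]
  dAB <- A - B
  if (sum(dAB^2) == 0)
    return(list(alpha = NA_real_, residual = NA_real_, verdict = NA_character_,
                flag = "identical_references"))
  alpha <- sum((q - B) * dAB) / sum(dAB^2)
  alpha <- min(max(alpha, 0), 1)
  fitted <- alpha * A + (1 - alpha) * B
  residual <- brayCurtis(q, fitted)
  verdict <- if (residual < cutoff && alpha >= 0.2 && alpha <= 0.8)
    "mixture_suspect" else "clean"
  list(alpha = alpha, residual = residual, verdict = verdict,
       flag = NA_character_)
}

#' Scan sequenced blank controls for swaps and mixtures
#'
#' Every sequenced false-positive control (a blank that amplified) and any
#' other queried unit is matched against the reference communities and
#' tested as a two-community mixture of its two closest references.
#'
#' @param table relative-mode [AbundanceTable-class].
#' @param references named list of reference profiles.
#' @param keys units to scan; defaults to flagged false-positive controls.
#' @param swap_cutoff dissimilarity below which a unit is called a swap.
#' @param mixture_cutoff residual cutoff passed to [fitMixture()].
#' @return data.frame, one row per scanned unit: best match, dissimilarity,
#'   mixture source pair, alpha, residual, verdict.
#' @export
anomalyScan <- function(table, references, keys = NULL, swap_cutoff = 0.05,
                        mixture_cutoff = 0.05) {
  stopifnot(is(table, "AbundanceTable"))
  info <- sampleInfo(table)
  if (is.null(keys))
    keys <- info$key[isTRUE_vec(info$false_positive_control)]
  rows <- lapply(keys, function(k) {
    q <- abundValues(table)[, k]
    mm <- matchComposition(q, references)
    if (!is.na(mm$flag) && mm$flag == "empty_query")
      return(data.frame(key = k, best = NA, dissimilarity = NA,
                        mix_A = NA, mix_B = NA, alpha = NA, residual = NA,
                        verdict = "clean", stringsAsFactors = FALSE))
    ord <- names(sort(mm$dissimilarities))
    fm <- if (length(ord) >= 2L)
      fitMixture(q, references[[ord[1L]]], references[[ord[2L]]],
                 cutoff = mixture_cutoff)
    else list(alpha = NA_real_, residual = NA_real_, verdict = "clean")
    verdict <- if (mm$dissimilarity < swap_cutoff) "swap_suspect"
               else if (identical(fm$verdict, "mixture_suspect"))
                 "mixture_suspect" else "clean"
    data.frame(key = k, best = mm$best, dissimilarity = mm$dissimilarity,
               mix_A = if (length(ord) >= 2L) ord[1L] else NA,
               mix_B = if (length(ord) >= 2L) ord[2L] else NA,
               alpha = fm$alpha, residual = fm$residual, verdict = verdict,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

isTRUE_vec <- function(x) !is.na(x) & x
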