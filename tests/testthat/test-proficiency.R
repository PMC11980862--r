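test_that("z-scores match their definition and zoning", {
  x <- c(A = 10, B = 12, C = 14)
  zs <- zScores(x)
  expect_equal(zs$mu, rep(12, 3))
  expect_equal(zs$sigma, rep(sd(x), 3))
  expect_equal(zs$z, (as.numeric(x) - 12) / sd(x), tolerance = 1e-12)
  expect_equal(zs$zone[zs$participant == "B"], "in_control")
  # |z| = 2 sits exactly on the in-control boundary
  zb <- zScores(c(A = 1, B = 2, C = 3))
  expect_true(all(abs(zb$z) <= 2))
  expect_error(zScores(c(A = 1, B = 2)), "3 participants")
})

test_that("zone cutoffs are 2 (warning) and 3 (action)", {
  # a single outlier can reach at most |z| = (n-1)/sqrt(n), so a panel of
  # 12 is the smallest all-else-equal panel that can cross the action line
  x <- setNames(c(rep(0, 11), 10), LETTERS[1:12])
  zs <- zScores(x)
  zL <- zs$z[zs$participant == "L"]
  expect_true(zL > 3)
  expect_equal(zs$zone[zs$participant == "L"], "action")
  # warning zone via construction: z = 2.5 must map to warning
  zone_of <- function(z) ifelse(abs(z) > 3, "action",
                                ifelse(abs(z) > 2, "warning", "in_control"))
  expect_equal(zone_of(2.5), "warning")
  expect_equal(zs$zone, zone_of(zs$z))
})

test_that("z-scores are invariant under affine transforms of the scores", {
  for (seed in 1:5) {
    set.seed(seed)
    x <- setNames(rnorm(8, 15, 0.5), LETTERS[1:8])
    z1 <- zScores(x)$z
    z2 <- zScores(3 * x + 7)$z
    expect_equal(z1, z2, tolerance = 1e-9)
  }
})

test_that("zero dispersion yields flagged all-zero z and a pass", {
  zs <- zScores(c(A = 20, B = 20, C = 20, D = 20))
  expect_true(attr(zs, "degenerate"))
  expect_equal(zs$z, rep(0, 4))
  expect_equal(unique(zs$zone), "in_control")
  v <- proficiencyVerdict(zs)
  expect_equal(v$verdict, "pass")
})

test_that("the verdict fails exactly on |z| > 3 and names offenders", {
  zs <- zScores(setNames(c(rep(0, 11), 9), LETTERS[1:12]))
  v <- proficiencyVerdict(zs)
  expect_equal(v$verdict, "fail")
  expect_equal(v$offenders, "L")
  ok <- zScores(c(A = 1, B = 2, C = 3))
  expect_equal(proficiencyVerdict(ok)$verdict, "pass")
  expect_error(proficiencyVerdict(ok[0, ]), "empty")
})

test_that("Youden classification follows the box/line rules", {
  zr <- c(sys = 3.5, tot = 3.5, ctl = 1.0, rnd = 2.0)
  zl <- c(sys = 3.4, tot = -3.5, ctl = 1.0, rnd = -2.0)
  yc <- youdenClassify(zr, zl)
  lab <- setNames(yc$label, yc$participant)
  expect_equal(lab[["sys"]], "systematic_error")
  expect_equal(lab[["tot"]], "total_error")
  expect_equal(lab[["ctl"]], "in_control")
  expect_equal(lab[["rnd"]], "random_error")   # |v| = 2sqrt(2) > 2, inside box
  u_ctl <- yc$u[yc$participant == "ctl"]
  expect_equal(u_ctl, sqrt(2), tolerance = 1e-12)
  expect_equal(yc$v[yc$participant == "ctl"], 0, tolerance = 1e-12)
  expect_equal(attr(yc, "circle_radius"), sqrt(qchisq(0.95, 2)))
})

test_that("the Youden rotation is an isometry", {
  for (seed in 1:10) {
    set.seed(seed)
    zr <- setNames(rnorm(6), LETTERS[1:6])
    zl <- setNames(rnorm(6), LETTERS[1:6])
    yc <- youdenClassify(zr, zl)
    expect_equal(yc$u^2 + yc$v^2, yc$z_river^2 + yc$z_lake^2,
                 tolerance = 1e-9)
  }
})

test_that("participants missing one pair member are skipped with a report", {
  yc <- youdenClassify(c(A = 1, B = 2), c(A = 1, C = 2))
  expect_equal(yc$participant, "A")
  expect_equal(sort(attr(yc, "skipped")), c("B", "C"))
})

test_that("the detection threshold matches the toy enumeration", {
  m <- cbind(`E1/A/L/1` = c(0.05, 0.008, 0.002, 0.940),
             `E1/B/L/1` = c(0.05, 0.008, 0.000, 0.942),
             `E1/C/L/1` = c(0.05, 0.000, 0.000, 0.950))
  rownames(m) <- c("big", "mid", "small", "filler")
  tab <- AbundanceTable(m, mode = "relative")
  dt <- detectionThreshold(tab)
  expect_equal(dt$threshold, 0.008)
  expect_true(all(!dt$per_taxon$missed[dt$per_taxon$taxon %in%
                                         c("big", "filler")]))
  # all-detected: threshold 0
  m2 <- m[c("big", "filler"), ]
  m2 <- sweep(m2, 2, colSums(m2), "/")
  expect_equal(detectionThreshold(AbundanceTable(m2, mode = "relative"))$threshold,
               0)
})

test_that("the threshold guarantee holds on simulated datasets", {
  # brute force: every taxon with representative abundance strictly above
  # the threshold must be present in all participants' tables
  for (seed in 1:5) {
    sim <- archetypeSimulation(seed = seed, n_labs = 5, reps = 1,
                               depth = 2000)
    rel <- toRelative(sim$table)
    info <- sampleInfo(rel)
    sub <- AbundanceTable(abundValues(rel)[, info$sample_type == "L"],
                          mode = "relative")
    dt <- detectionThreshold(sub)
    m <- abundValues(sub)
    present_all <- rowSums(m > 0) == ncol(m)
    above <- dt$per_taxon$representative > dt$threshold
    expect_true(all(present_all[above]))
  }
})

test_that("mean-representative variant stays below the max variant", {
  sim <- archetypeSimulation(seed = 3, n_labs = 5, reps = 1, depth = 2000)
  rel <- toRelative(sim$table)
  info <- sampleInfo(rel)
  sub <- AbundanceTable(abundValues(rel)[, info$sample_type == "R"],
                        mode = "relative")
  t_max <- detectionThreshold(sub, "max")
  t_mean <- detectionThreshold(sub, "mean")
  expect_true(all(t_mean$per_taxon$representative <=
                    t_max$per_taxon$representative + 1e-12))
})

test_that("composition matching identifies references exactly and under noise", {
  prof <- makeReferenceCommunities(seed = 31)
  refs <- prof[c("L", "R", "M")]
  expect_equal(matchComposition(prof$L, refs)$best, "L")
  expect_equal(matchComposition(prof$L, refs)$dissimilarity, 0,
               tolerance = 1e-12)
  expect_equal(matchComposition(prof$R, refs)$best, "R")
  # empty query is flagged
  em <- matchComposition(setNames(numeric(2), c("a", "b")), refs)
  expect_true(is.na(em$best))
  expect_equal(em$flag, "empty_query")
  # a noisy L at depth 1e5 still matches L closely
  d <- designSpec(list(list(id = "E1", material = "biofilm",
                            participants = "A", replicates = 1,
                            sample_types = "L")))
  truth <- syntheticTruth(prof, list(A = labEffect("A", random_sd = 0.05)),
                          depth = 1e5, seed = 17)
  rel <- toRelative(simulateDataset(d, truth)$table)
  q <- abundValues(rel)[, 1]
  mm <- matchComposition(q[q > 0], refs)
  expect_equal(mm$best, "L")
  expect_lt(mm$dissimilarity, 0.05)
})

test_that("mixture fitting recovers exact mixtures and endpoints", {
  prof <- makeReferenceCommunities(seed = 32)
  uni <- union(names(prof$L), names(prof$M))
  pad <- function(p) { v <- setNames(numeric(length(uni)), uni)
                       v[names(p)] <- p; v }
  q <- 0.5 * pad(prof$L) + 0.5 * pad(prof$M)
  fm <- fitMixture(q, prof$L, prof$M)
  expect_equal(fm$alpha, 0.5, tolerance = 1e-9)
  expect_equal(fm$residual, 0, tolerance = 1e-9)
  expect_equal(fm$verdict, "mixture_suspect")
  fe <- fitMixture(prof$L, prof$L, prof$M)
  expect_equal(fe$alpha, 1, tolerance = 1e-9)
  expect_equal(fe$residual, 0, tolerance = 1e-9)
  expect_equal(fe$verdict, "clean")            # alpha outside [0.2, 0.8]
  dup <- fitMixture(q, prof$L, prof$L)
  expect_true(is.na(dup$alpha))
  expect_equal(dup$flag, "identical_references")
})

test_that("closed-form mixture alpha agrees with a grid search", {
  prof <- makeReferenceCommunities(seed = 33)
  uni <- union(names(prof$L), names(prof$M))
  pad <- function(p) { v <- setNames(numeric(length(uni)), uni)
                       v[names(p)] <- p; v }
  A <- pad(prof$L); B <- pad(prof$M)
  grid <- seq(0, 1, by = 0.01)
  for (seed in 1:5) {
    set.seed(seed)
    true_a <- runif(1, 0.1, 0.9)
    q <- true_a * A + (1 - true_a) * B + abs(rnorm(length(uni), 0, 1e-3))
    q <- q / sum(q)
    ssq <- vapply(grid, function(a) sum((q - (a * A + (1 - a) * B))^2), 0)
    a_grid <- grid[which.min(ssq)]
    fm <- fitMixture(q, A, B)
    expect_lt(abs(fm$alpha - a_grid), 0.01 + 1e-9)
  }
})

test_that("anomalyScan diagnoses swapped blanks and mixed samples", {
  prof <- makeReferenceCommunities(seed = 34)
  d <- designSpec(list(list(id = "E1", material = "biofilm",
                            participants = c("E", "I"), replicates = 1,
                            sample_types = c("L", "W"))))
  eff <- list(E = labEffect("E", random_sd = 0.02),
              I = labEffect("I", random_sd = 0.02))
  anoms <- list(anomalySpec("E1/E/W/1", "swap", "L"),
                anomalySpec("E1/I/L/1", "mixture", c("L", "M"), 0.5))
  truth <- syntheticTruth(prof, eff, anomalies = anoms, depth = 1e5,
                          seed = 55)
  sim <- simulateDataset(d, truth)
  rel <- toRelative(sim$table)
  scan <- anomalyScan(rel, prof[c("L", "R", "M")],
                      keys = c("E1/E/W/1", "E1/I/L/1"))
  expect_equal(scan$verdict[scan$key == "E1/E/W/1"], "swap_suspect")
  expect_equal(scan$best[scan$key == "E1/E/W/1"], "L")
  expect_equal(scan$verdict[scan$key == "E1/I/L/1"], "mixture_suspect")
  expect_equal(scan$alpha[scan$key == "E1/I/L/1"], 0.5, tolerance = 0.05)
})
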