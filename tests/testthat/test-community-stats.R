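test_that("Bray-Curtis matches its closed form and edge cases", {
  expect_equal(brayCurtis(c(0.7, 0.3, 0), c(0.3, 0.3, 0.4)), 0.4,
               tolerance = 1e-12)
  expect_equal(brayCurtis(c(0.5, 0.5), c(0.5, 0.5)), 0)
  expect_equal(brayCurtis(c(1, 0), c(0, 1)), 1)
  bc <- brayCurtis(c(0, 0), c(0, 0))
  expect_true(is.na(bc) && attr(bc, "undefined"))
})

test_that("Bray-Curtis is symmetric with identity of indiscernibles", {
  for (seed in 1:10) {
    x <- randomProfile(6, seed)
    y <- randomProfile(6, seed + 100)
    expect_equal(brayCurtis(x, y), brayCurtis(y, x), tolerance = 1e-12)
    expect_equal(brayCurtis(x, x), 0, tolerance = 1e-12)
    expect_true(brayCurtis(x, y) >= 0 && brayCurtis(x, y) <= 1)
  }
})

test_that("the distance matrix agrees with pairwise closed forms", {
  tab <- multiLabTable(n_labs = 5, seed = 4)
  D <- as.matrix(brayCurtisMatrix(tab))
  m <- abundValues(tab)
  expect_equal(D["E1/A/L/1", "E1/C/L/1"],
               brayCurtis(m[, "E1/A/L/1"], m[, "E1/C/L/1"]),
               tolerance = 1e-12)
  expect_equal(diag(D), setNames(rep(0, 5), colnames(m)))
  expect_equal(D, t(D), tolerance = 1e-12)
})

test_that("PERMANOVA gives R2 = 1 for perfectly repeated distinct groups", {
  p1 <- randomProfile(6, 1); p2 <- randomProfile(6, 2)
  m <- cbind(a1 = p1, a2 = p1, a3 = p1, b1 = p2, b2 = p2, b3 = p2)
  D <- as.matrix(vegan::vegdist(t(m), "bray"))
  res <- permanovaTest(D, rep(c("a", "b"), each = 3), seed = 1)
  expect_equal(res$R2, 1, tolerance = 1e-9)
  expect_true(res$exhaustive)            # 6! = 720 permutations enumerated
  # ties: every permutation preserving the partition attains the same F,
  # so the exact p equals 2 * 3! * 3! / 6! = 0.1
  expect_lte(res$p, 0.1)
})

test_that("PERMANOVA partition satisfies R2 + SSw/SSt = 1 and matches vegan", {
  for (seed in 1:3) {
    sim <- archetypeSimulation(seed = seed, n_labs = 4, reps = 3,
                               depth = 3000)
    rel <- toRelative(sim$table)
    info <- sampleInfo(rel)
    sel <- info$sample_type == "L"
    m <- abundValues(rel)[, sel]
    grp <- info$participant[sel]
    D <- vegan::vegdist(t(m), "bray")
    res <- permanovaTest(D, grp, n_perm = 199, seed = seed)
    # independent route: vegan's adonis2 on the same distances
    ref <- vegan::adonis2(D ~ grp, data = data.frame(grp = grp),
                          permutations = 99)
    expect_equal(res$statistic, ref$F[1], tolerance = 1e-9)
    expect_equal(res$R2, ref$R2[1], tolerance = 1e-9)
  }
})

test_that("degenerate all-zero distances are flagged", {
  D <- matrix(0, 4, 4)
  res <- permanovaTest(D, c("a", "a", "b", "b"), seed = 1)
  expect_equal(res$flag, "degenerate_distances")
  expect_true(is.na(res$p))
})

test_that("Monte-Carlo and exhaustive PERMANOVA p agree within 2 SEs", {
  set.seed(41)
  m <- matrix(rexp(7 * 5), 5, 7)
  m <- sweep(m, 2, colSums(m), "/")
  D <- vegan::vegdist(t(m), "bray")
  grp <- c("a", "a", "a", "b", "b", "b", "b")
  exact <- permanovaTest(D, grp)            # n = 7 -> exhaustive
  expect_true(exact$exhaustive)
  # Monte-Carlo route: sample label permutations and recompute pseudo-F
  n_mc <- 2000
  set.seed(99)
  D2 <- as.matrix(D)^2
  f_obs <- exact$statistic
  f_mc <- replicate(n_mc,
    diatomRing:::permanova_stats(D2, grp[sample(7)])$F)
  p_mc <- (1 + sum(f_mc >= f_obs - 1e-12)) / (1 + n_mc)
  se <- sqrt(exact$p * (1 - exact$p) / n_mc)
  expect_lt(abs(p_mc - exact$p), 2 * se + 1 / n_mc)
})

test_that("PERMANOVA p is null-calibrated on structureless data", {
  # with exchangeable labels the exhaustive p is (near) uniform: check its
  # mean over seeds sits in the middle half
  ps <- vapply(1:20, function(seed) {
    set.seed(seed)
    m <- matrix(rexp(6 * 8), 8, 6)
    D <- vegan::vegdist(t(m), "bray")
    permanovaTest(D, rep(c("a", "b"), each = 3))$p
  }, 0)
  expect_gt(mean(ps), 0.25)
  expect_gt(min(ps), 1 / 720 - 1e-12)
})

test_that("MRPP boundaries: identical structure gives A ~ 0, separation A = 1", {
  # same composition in both groups -> no group effect
  as <- vapply(1:5, function(seed) {
    set.seed(seed)
    m <- matrix(rexp(6 * 8), 8, 6)
    D <- vegan::vegdist(t(m), "bray")
    mrppTest(D, rep(c("a", "b"), 3), seed = seed)$A
  }, 0)
  expect_lt(max(abs(as)), 0.25)
  expect_lt(abs(mean(as)), 0.1)
  # perfectly separated repeated groups: delta = 0, A = 1
  p1 <- randomProfile(5, 1); p2 <- randomProfile(5, 2)
  m <- cbind(a1 = p1, a2 = p1, b1 = p2, b2 = p2)
  D <- vegan::vegdist(t(m), "bray")
  res <- mrppTest(D, c("a", "a", "b", "b"), seed = 1)
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$A, 1, tolerance = 1e-9)
})

test_that("MRPP delta and A match vegan's mrpp", {
  sim <- archetypeSimulation(seed = 5, n_labs = 4, reps = 2, depth = 3000)
  rel <- toRelative(sim$table)
  info <- sampleInfo(rel)
  sel <- info$sample_type == "R"
  m <- abundValues(rel)[, sel]
  grp <- info$participant[sel]
  D <- vegan::vegdist(t(m), "bray")
  res <- mrppTest(D, grp, n_perm = 99, seed = 7)
  ref <- vegan::mrpp(D, grp, permutations = 49)
  expect_equal(res$statistic, ref$delta, tolerance = 1e-9)
  expect_equal(res$A, ref$A, tolerance = 1e-9)
})

test_that("MRPP excludes singleton groups with a report", {
  p <- lapply(1:5, function(s) randomProfile(5, s))
  m <- do.call(cbind, p)
  colnames(m) <- paste0("s", 1:5)
  D <- vegan::vegdist(t(m), "bray")
  res <- mrppTest(D, c("a", "a", "b", "b", "c"), seed = 1)
  expect_match(res$flag, "c")
  expect_true(is.finite(res$A))
})

test_that("Monte-Carlo and exhaustive MRPP p agree within 2 SEs", {
  set.seed(77)
  m <- matrix(rexp(6 * 5), 5, 6)
  D <- vegan::vegdist(t(m), "bray")
  grp <- c("a", "a", "a", "b", "b", "b")
  exact <- mrppTest(D, grp)
  expect_true(exact$exhaustive)
  n_mc <- 2000
  set.seed(11)
  Dm <- as.matrix(D)
  d_mc <- replicate(n_mc,
    diatomRing:::mrpp_delta(Dm, grp[sample(6)], c("a", "b")))
  p_mc <- (1 + sum(d_mc <= exact$statistic + 1e-12)) / (1 + n_mc)
  se <- sqrt(exact$p * (1 - exact$p) / n_mc)
  expect_lt(abs(p_mc - exact$p), 2 * se + 1 / n_mc)
})

test_that("nMDS embeds an embeddable triangle with near-zero stress", {
  pts <- rbind(c(0, 0), c(1, 0), c(0.4, 0.8))
  D <- dist(pts)
  res <- nmdsOrdination(D, k = 2, restarts = 5, seed = 3)
  expect_lt(res$stress, 0.01)
  expect_equal(colMeans(res$points), c(0, 0), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("nMDS is deterministic given the seed", {
  sim <- archetypeSimulation(seed = 6, n_labs = 4, reps = 2, depth = 2000)
  rel <- toRelative(sim$table)
  info <- sampleInfo(rel)
  m <- abundValues(rel)[, info$sample_type == "L"]
  D <- vegan::vegdist(t(m), "bray")
  r1 <- nmdsOrdination(D, seed = 42)
  r2 <- nmdsOrdination(D, seed = 42)
  expect_identical(r1$points, r2$points)
  expect_identical(r1$stress, r2$stress)
})

test_that("Kruskal-Wallis matches the exact rank computation for separated groups", {
  # two groups of 3 with completely separated ranks: H = 12/(n(n+1)) *
  # sum n_i (rbar_i - rbar)^2 = 12/42 * (3*(2-3.5)^2 + 3*(5-3.5)^2)
  vals <- c(1, 2, 3, 10, 11, 12)
  grp <- rep(c("lo", "hi"), each = 3)
  res <- kruskalWallisTest(vals, grp)
  H_hand <- 12 / (6 * 7) * (3 * (2 - 3.5)^2 + 3 * (5 - 3.5)^2)
  expect_equal(res$H, H_hand, tolerance = 1e-12)
  expect_equal(res$df, 1)
  expect_equal(res$p, stats::pchisq(H_hand, 1, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("Kruskal-Wallis chi-squared p is close to a permutation p", {
  set.seed(21)
  vals <- c(rnorm(4, 0), rnorm(4, 1.5))
  grp <- rep(c("a", "b"), each = 4)
  res <- kruskalWallisTest(vals, grp)
  n_mc <- 4000
  h_mc <- replicate(n_mc, kruskalWallisTest(vals, sample(grp))$H)
  p_perm <- (1 + sum(h_mc >= res$H - 1e-12)) / (1 + n_mc)
  # the chi-squared approximation is coarse at n = 8; one decimal suffices
  expect_lt(abs(p_perm - res$p), 0.1)
})

test_that("identical values give H = 0, p = 1", {
  res <- kruskalWallisTest(rep(5, 6), rep(c("a", "b"), 3))
  expect_equal(res$H, 0)
  expect_equal(res$p, 1)
})
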