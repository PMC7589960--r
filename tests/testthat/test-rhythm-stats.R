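# Distance matrices, two-way PERMANOVA, pairwise contrasts, ANOVA, SNK
# and diagnostics.

test_that("distanceMatrix matches a double-loop oracle", {
  m <- rbind(c(0, 0), c(3, 4))
  D <- distanceMatrix(m, normalise = FALSE)
  expect_equal(D[1, 2], 5)
  expect_equal(D[1, 1], 0)

  set.seed(2)
  X <- matrix(rnorm(30), 10, 3)
  D2 <- distanceMatrix(X, normalise = FALSE)
  for (i in 1:10) for (j in 1:10)
    expect_equal(D2[i, j], sqrt(sum((X[i, ] - X[j, ])^2)),
                 tolerance = 1e-12)
  expect_equal(D2, t(D2))

  Xz <- cbind(X, 0)
  expect_warning(Dz <- distanceMatrix(Xz, normalise = TRUE),
                 "zero-variance")
  expect_equal(Dz, distanceMatrix(X, normalise = TRUE))
})

test_that("PERMANOVA df columns reproduce the two crossed designs", {
  set.seed(5)
  l1 <- balancedLayout(2, 6, 3)
  D1 <- distanceMatrix(matrix(rnorm(l1$n * 3), l1$n), normalise = FALSE)
  t1 <- resultTable(permanovaTwoWay(D1, l1$fa, l1$fb, nPerm = 999,
                                    seed = 1))
  expect_equal(t1$df, c(1, 5, 5, 24, 35))

  l2 <- balancedLayout(2, 4, 3)
  D2 <- distanceMatrix(matrix(rnorm(l2$n * 3), l2$n), normalise = FALSE)
  t2 <- resultTable(permanovaTwoWay(D2, l2$fa, l2$fb, nPerm = 999,
                                    seed = 1))
  expect_equal(t2$df, c(1, 3, 3, 16, 23))
  expect_equal(t2$df[t2$source == "Residual"], 16)
})

test_that("univariate-Euclidean pseudo-F equals the classical ANOVA F", {
  for (seed in 1:5) {
    set.seed(seed)
    l <- balancedLayout(2, 3, 3)
    y <- rnorm(l$n, mean = as.numeric(l$fa))
    D <- as.matrix(dist(matrix(y)))
    pm <- resultTable(permanovaTwoWay(D, l$fa, l$fb, nPerm = 999,
                                      seed = seed))
    cl <- anovaTwoWay(y, l$fa, l$fb)
    expect_equal(pm$pseudo_F[1:3], cl$F[1:3], tolerance = 1e-9)
    expect_equal(pm$SS[1:4], cl$SS, tolerance = 1e-9)
  }
})

test_that("the SS partition is conserved and degenerate input errors", {
  set.seed(7)
  l <- balancedLayout(2, 4, 3)
  Y <- matrix(rnorm(l$n * 4), l$n)
  tab <- resultTable(permanovaTwoWay(distanceMatrix(Y), l$fa, l$fb,
                                     nPerm = 999, seed = 2))
  expect_equal(sum(tab$SS[1:4]), tab$SS[5], tolerance = 1e-9)
  expect_equal(sum(tab$df[1:4]), tab$df[5])

  Dz <- matrix(0, l$n, l$n)
  expect_error(permanovaTwoWay(Dz, l$fa, l$fb, nPerm = 999, seed = 1),
               "zero")
  expect_error(permanovaTwoWay(distanceMatrix(Y), l$fa, l$fb,
                               nPerm = 99, seed = 1), "999")
})

test_that("PERMANOVA agrees with an independent implementation", {
  set.seed(11)
  l <- balancedLayout(2, 3, 4)
  Y <- matrix(rnorm(l$n * 3), l$n)
  D <- distanceMatrix(Y, normalise = FALSE)
  mine <- resultTable(permanovaTwoWay(D, l$fa, l$fb, nPerm = 999,
                                      seed = 3))
  ref <- vegan::adonis2(stats::as.dist(D) ~ a * b,
                        data = data.frame(a = l$fa, b = l$fb),
                        permutations = 99, by = "terms")
  expect_equal(mine$SS, ref$SumOfSqs, tolerance = 1e-9)
  expect_equal(mine$pseudo_F[1:3], ref$F[1:3], tolerance = 1e-9)
})

test_that("unrestricted-permutation p-values are exchangeable-null valid", {
  # quick sanity check at modest replication; the full calibration runs
  # in the acceptance suite
  set.seed(13)
  l <- balancedLayout(2, 3, 2)
  hits <- 0
  for (i in 1:60) {
    y <- rnorm(l$n)
    p <- resultTable(permanovaTwoWay(as.matrix(dist(matrix(y))), l$fa,
                                     l$fb, nPerm = 999,
                                     seed = i))$p_perm[1]
    hits <- hits + (p <= 0.05)
  }
  expect_lte(hits / 60, 0.12)
})

test_that("pairwise contrasts enumerate exhaustively and match t", {
  set.seed(17)
  g1 <- rnorm(3); g2 <- rnorm(3) + 2
  y <- c(g1, g2)
  D <- as.matrix(dist(matrix(y)))
  grp <- factor(rep("all", 6))
  lev <- factor(rep(c("t1", "t2"), each = 3))
  pw <- pairwisePermanova(D, grp, lev, seed = 1)
  expect_equal(pw$n_unique_perms, 10)  # C(6,3)/2 distinct splits
  expect_true(pw$low_resolution)
  # oracle: enumerate all 20 assignments by hand
  fObs <- pw$t^2
  fAll <- apply(combn(6, 3), 2, function(ix) {
    lab <- rep(2, 6); lab[ix] <- 1
    m6ARhythms:::.twoGroupF(m6ARhythms:::.gowerCenter(D), lab)
  })
  expect_equal(pw$p_perm, mean(fAll >= fObs - 1e-12), tolerance = 1e-12)
  # t equals the classical equal-variance two-sample t
  tt <- t.test(g1, g2, var.equal = TRUE)
  expect_equal(pw$t, abs(unname(tt$statistic)), tolerance = 1e-9)
  # identical groups: t ~ 0, p_perm 1 within resolution
  yEq <- rep(c(1, 2, 3), 2)
  DEq <- as.matrix(dist(matrix(yEq)))
  pwEq <- pairwisePermanova(DEq, grp, lev, seed = 1)
  expect_lt(pwEq$t, 1e-6)
  expect_equal(pwEq$p_perm, 1)
})

test_that("Monte-Carlo p approximates the t-distribution when univariate", {
  set.seed(19)
  g1 <- rnorm(5); g2 <- rnorm(5) + 1.5
  D <- as.matrix(dist(matrix(c(g1, g2))))
  pw <- pairwisePermanova(D, factor(rep("x", 10)),
                          factor(rep(c("a", "b"), each = 5)),
                          nMc = 50000, seed = 4)
  tt <- t.test(g1, g2, var.equal = TRUE)
  # univariate: the centred matrix is rank one, so the draw is exactly
  # F(1, n-2); agreement up to Monte-Carlo error
  expect_lt(abs(pw$p_mc - tt$p.value), 0.003)
})

test_that("two-way ANOVA reproduces hand-computed partitions", {
  # 2 x 2 x 2 toy with known cell means
  fa <- factor(rep(c("u", "v"), each = 4))
  fb <- factor(rep(rep(c("x", "y"), each = 2), 2))
  y <- c(1, 3, 2, 4, 5, 7, 8, 10)
  tab <- anovaTwoWay(y, fa, fb)
  gm <- mean(y)
  ssA <- 4 * sum((tapply(y, fa, mean) - gm)^2)
  ssB <- 4 * sum((tapply(y, fb, mean) - gm)^2)
  cell <- tapply(y, interaction(fa, fb), mean)
  ssCells <- 2 * sum((cell - gm)^2)
  ssAB <- ssCells - ssA - ssB
  ssE <- sum((y - rep(cell[interaction(fa, fb)], 1))^2)
  expect_equal(tab$SS, c(ssA, ssB, ssAB, ssE), tolerance = 1e-9)
  expect_equal(sum(tab$df), length(y) - 1)

  l <- balancedLayout(2, 4, 3)
  set.seed(23)
  t2 <- anovaTwoWay(rnorm(l$n), l$fa, l$fb)
  expect_equal(t2$df[t2$effect == "Error"], 16)

  expect_warning(tc <- anovaTwoWay(rep(1, l$n), l$fa, l$fb), "zero")
  expect_true(attr(tc, "degenerate"))
})

test_that("SNK declares far means different and equal means homogeneous", {
  s0 <- snkPosthoc(c(a = 1, b = 1, c = 1), mse = 1, dfError = 12, n = 3)
  expect_false(any(s0$decisions$significant))
  expect_identical(length(s0$groups), 1L)

  # two means separated by 10 * sqrt(MSE/n) exceed q(0.05, 2, df)
  s2 <- snkPosthoc(c(a = 0, b = 10 * sqrt(1 / 3)), mse = 1, dfError = 12,
                   n = 3)
  expect_true(s2$decisions$significant)
  expect_gt(s2$decisions$q, qtukey(0.95, 2, 12))
})

test_that("SNK follows the stepwise rule on a worked three-mean example", {
  # MSE 0.4, n = 5, df = 12: se = sqrt(0.4/5) = 0.2828
  # means 6.0, 6.7, 7.2: q13 = 4.243 > q(0.05,3,12) = 3.773 -> extremes
  # differ; q12 = 2.475 < q(0.05,2,12) = 3.082 -> ns;
  # q23 = 1.768 < 3.082 -> ns
  s <- snkPosthoc(c(m1 = 6.0, m2 = 6.7, m3 = 7.2), mse = 0.4,
                  dfError = 12, n = 5)
  d <- s$decisions
  expect_equal(d$q[d$level_1 == "m1" & d$level_2 == "m3"],
               (7.2 - 6.0) / sqrt(0.4 / 5), tolerance = 1e-9)
  expect_true(d$significant[d$level_1 == "m1" & d$level_2 == "m3"])
  expect_false(d$significant[d$level_1 == "m1" & d$level_2 == "m2"])
  expect_false(d$significant[d$level_1 == "m2" & d$level_2 == "m3"])
  expect_identical(length(s$groups), 2L)

  # stepwise gating: inner pairs of an accepted span stay untested
  sFlat <- snkPosthoc(c(a = 0, b = 0.05, c = 0.1), mse = 1, dfError = 20,
                      n = 5)
  inner <- sFlat$decisions$span == 2
  expect_false(any(sFlat$decisions$tested[inner]))
  expect_false(any(sFlat$decisions$significant))

  expect_error(snkPosthoc(c(a = 1, b = 2), 1, 10, 3, alpha = 1.2),
               "alpha")
})

test_that("SNK homogeneous groups are coherent with pairwise decisions", {
  set.seed(29)
  for (i in 1:20) {
    k <- sample(3:6, 1)
    means <- setNames(sort(rnorm(k, sd = 2)), letters[seq_len(k)])
    s <- snkPosthoc(means, mse = 1, dfError = 16, n = 3)
    for (g in s$groups) {
      if (length(g) < 2) next
      d <- s$decisions
      inGroup <- d$level_1 %in% g & d$level_2 %in% g
      expect_false(any(d$significant[inGroup]))
    }
  }
})

test_that("diagnostics report Shapiro-Wilk and mean-centred Levene", {
  set.seed(31)
  r <- rnorm(50)
  g <- gl(2, 25)
  out <- assumptionChecks(r, g)
  expect_gt(out$shapiro$W, 0.9)
  ref <- car::leveneTest(r ~ g, center = mean)
  expect_equal(out$levene$F, ref[["F value"]][1])

  # identical distributions across groups -> Levene statistic 0
  same <- c(rnorm(10), rnorm(10))
  same[11:20] <- same[1:10]
  outSame <- assumptionChecks(same, gl(2, 10))
  expect_equal(outSame$levene$F, 0, tolerance = 1e-12)

  expect_warning(deg <- assumptionChecks(rep(1, 10), gl(2, 5)),
                 "identical")
  expect_true(deg$degenerate)
})

test_that("Levene detects strong variance heterogeneity reliably", {
  hits <- 0
  for (i in 1:200) {
    set.seed(4000 + i)
    y <- c(rnorm(30, sd = 1), rnorm(30, sd = sqrt(10)))
    out <- assumptionChecks(y, gl(2, 30))
    hits <- hits + (out$levene$p < 0.05)
  }
  expect_gte(hits / 200, 0.95)
})
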