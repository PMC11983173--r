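test_that("standardization gives population z-scores and drops constants", {
  z <- standardizeFeatures(cbind(a = c(1, 2, 3)))
  expect_equal(as.numeric(z), c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-9)
  expect_equal(sqrt(3 / 2), 1.224745, tolerance = 1e-6)

  expect_warning(z2 <- standardizeFeatures(cbind(a = c(1, 2, 3),
                                                 b = c(5, 5, 5))),
                 "constant feature")
  expect_equal(ncol(z2), 1)
  expect_error(suppressWarnings(standardizeFeatures(cbind(b = c(5, 5, 5)))),
               "nothing to cluster")

  spec <- syntheticSpec(n_residues = 12, n_frames = 60, seed = 2)
  fm <- buildFeatures(generateSystem(spec)$trajectory,
                      contact_residues = syntheticContacts(spec))
  expect_true(all(abs(colMeans(fm)) < 1e-9))
  expect_true(all(abs(sqrt(colMeans(fm^2)) - 1) < 1e-9))
})

test_that("a static trajectory yields no usable features", {
  spec <- syntheticSpec(n_residues = 10, n_frames = 12, noise_sigma = 0,
                        tail_flex = 0, drift_sigma = 0, n_modes = 1,
                        mode_fractions = 1, seed = 1)
  g <- generateSystem(spec)
  expect_error(suppressWarnings(
    buildFeatures(g$trajectory, contact_residues = syntheticContacts(spec))),
    "nothing to cluster")
})

test_that("PCA retains the minimal component count for the variance target", {
  set.seed(5)
  # data exactly on a line embedded in 5-D
  line <- outer(rnorm(40), c(1, -2, 0.5, 3, 1))
  r1 <- pcaReduce(line, 0.90)
  expect_equal(attr(r1, "n_components"), 1L)
  expect_equal(attr(r1, "explained")[1], 1, tolerance = 1e-9)

  # spectrum {6, 3, 1}: ratios 0.6 / 0.3 / 0.1 -> exactly 2 components
  n <- 120
  Z <- qr.Q(qr(scale(matrix(rnorm(n * 3), n, 3), scale = FALSE)))
  X <- Z %*% diag(sqrt((n - 1) * c(6, 3, 1)))
  ev <- eigen(cov(X))$values
  expect_equal(ev, c(6, 3, 1), tolerance = 1e-8)
  r2 <- pcaReduce(X, 0.90)
  expect_equal(attr(r2, "n_components"), 2L)
  expect_gte(sum(attr(r2, "explained")[1:2]), 0.90 - 1e-12)

  # isotropic 3-D Gaussian needs all 3 components at 0.90
  iso <- matrix(rnorm(1500), 500, 3)
  expect_equal(attr(pcaReduce(iso, 0.90), "n_components"), 3L)

  # retained variance meets the target on random fixtures
  for (i in 1:5) {
    Xr <- matrix(rnorm(60 * 6), 60, 6) %*% diag(runif(6, 0.2, 3))
    rr <- pcaReduce(Xr, 0.90)
    expect_gte(sum(attr(rr, "explained")[seq_len(attr(rr, "n_components"))]),
               0.90 - 1e-12)
    # minimality
    if (attr(rr, "n_components") > 1)
      expect_lt(sum(attr(rr, "explained")[
        seq_len(attr(rr, "n_components") - 1)]), 0.90)
  }
  expect_error(pcaReduce(matrix(1, 1, 3)), "at least 2")
})

test_that("validation indices match hand-computed values on four points", {
  x <- rbind(c(0, 0), c(1, 0), c(10, 0), c(11, 0))
  idx <- validationIndices(x, c(1L, 1L, 2L, 2L))
  # silhouette: points at the segment ends score 9.5/10.5, inner 8.5/9.5
  expect_equal(unname(idx["SI"]), (19 / 21 + 17 / 19) / 2, tolerance = 1e-9)
  expect_equal(unname(idx["DI"]), 9, tolerance = 1e-9)
  expect_equal(unname(idx["pSF"]), 200, tolerance = 1e-9)
  expect_equal(unname(idx["WSS"]), 1, tolerance = 1e-9)

  # k = n: every point its own cluster, WSS exactly 0
  expect_equal(unname(validationIndices(x, 1:4)["WSS"]), 0)

  # single tight blob (no structure): silhouette stays low for any k
  set.seed(8)
  blob <- matrix(rnorm(500, sd = 0.05), 100, 5)
  scan <- kscan(blob, k_min = 2, k_max = 3, n_init = 5, seed = 1)
  expect_true(all(scan$SI < 0.3))
})

test_that("kscan WSS decreases in k and k selection follows the 3-of-4 rule", {
  set.seed(3)
  x <- rbind(matrix(rnorm(120, sd = 0.3), 60, 2),
             sweep(matrix(rnorm(60, sd = 0.3), 30, 2), 2, c(6, 0), `+`),
             sweep(matrix(rnorm(40, sd = 0.3), 20, 2), 2, c(0, 6), `+`))
  scan <- kscan(x, k_min = 2, k_max = 8, n_init = 5, seed = 4)
  expect_true(all(diff(scan$WSS) <= 1e-9))
  expect_true(all(scan$SI >= -1 & scan$SI <= 1))
  expect_true(all(scan$DI > 0))
  expect_equal(as.integer(selectK(scan)), 3L)
  expect_error(kscan(x[1:5, ], k_min = 2, k_max = 10), "exceeds")
})

test_that("selectK voting: unanimous, 3-of-4 and fallback paths", {
  fake <- function(SI, DI, pSF, WSS) {
    structure(data.frame(k = seq(2, 1 + length(SI)), SI = SI, DI = DI,
                         pSF = pSF, WSS = WSS),
              class = c("KScanTable", "data.frame"))
  }
  # all four criteria agree on k = 3
  s1 <- fake(SI = c(.2, .8, .4, .3), DI = c(.1, .9, .2, .2),
             pSF = c(10, 90, 40, 30), WSS = c(100, 40, 35, 33))
  expect_equal(as.integer(selectK(s1)), 3L)
  expect_match(attr(selectK(s1), "decision"), "3-of-4")

  # SI and pSF peak at 4, DI at 2, WSS elbow at 4 -> 3 votes for 4
  s2 <- fake(SI = c(.2, .3, .5, .4), DI = c(.9, .5, .4, .3),
             pSF = c(10, 20, 50, 40), WSS = c(100, 60, 30, 29))
  expect_equal(as.integer(selectK(s2)), 4L)

  # 2-2 split with no 3-vote winner: smaller k wins the tie
  s3 <- fake(SI = c(.8, .3, .2, .2), DI = c(.9, .2, .2, .2),
             pSF = c(10, 20, 90, 40), WSS = c(100, 99, 50, 49))
  expect_equal(as.integer(selectK(s3)), 2L)
  expect_match(attr(selectK(s3), "decision"), "most votes")
})

test_that("fitModel reports descending integer weights and true centroids", {
  set.seed(13)
  x <- rbind(matrix(rnorm(122, sd = 0.25), 61, 2),
             sweep(matrix(rnorm(46, sd = 0.25), 23, 2), 2, c(5, 0), `+`),
             sweep(matrix(rnorm(32, sd = 0.25), 16, 2), 2, c(0, 5), `+`))
  m <- fitModel(x, 3, seed = 2)
  expect_equal(m$weights_pct, c(61, 23, 16))
  expect_equal(sum(m$weights_frac), 1, tolerance = 1e-12)
  expect_equal(sort(unique(m$labels)), 1:3)

  # centroid frame carries its own cluster's label and is the nearest
  # member to the cluster mean (checked exhaustively)
  for (c_ in 1:3) {
    cf <- m$centroid_frames[c_]
    expect_equal(m$labels[cf], c_)
    ic <- which(m$labels == c_)
    d2 <- rowSums(sweep(x[ic, , drop = FALSE], 2, m$centers[c_, ])^2)
    expect_equal(sum((x[cf, ] - m$centers[c_, ])^2), min(d2),
                 tolerance = 1e-12)
  }

  # degenerate single-cluster case
  ones <- matrix(1, 20, 2)
  m1 <- fitModel(ones, 1)
  expect_equal(m1$weights_pct, 100L)
  expect_equal(m1$centroid_frames, 1L)
})

test_that("pipeline is deterministic and invariant to column order/rescaling", {
  spec <- syntheticSpec(n_residues = 14, n_frames = 150, seed = 6)
  g <- generateSystem(spec)
  run <- function() {
    clusterBindingModes(g$trajectory,
                        contact_residues = syntheticContacts(spec),
                        k_max = 6, seed = 31)
  }
  r1 <- run(); r2 <- run()
  expect_identical(r1$model$labels, r2$model$labels)
  expect_identical(r1$model$weights_pct, r2$model$weights_pct)
  expect_identical(r1$model$centroid_frames, r2$model$centroid_frames)
  expect_equal(as.data.frame(r1$scan), as.data.frame(r2$scan))

  # column order and affine rescaling of raw features do not matter
  raw <- cbind(a = rnorm(80), b = rnorm(80, sd = 4), c = runif(80))
  z1 <- pcaReduce(standardizeFeatures(raw), 0.95)
  perm <- raw[, c(2, 3, 1)]
  resc <- raw; resc[, 2] <- -3.5 * resc[, 2] + 7
  z2 <- pcaReduce(standardizeFeatures(perm), 0.95)
  z3 <- pcaReduce(standardizeFeatures(resc), 0.95)
  m1 <- fitModel(z1, 3, seed = 5)
  expect_equal(ari(m1$labels, fitModel(z2, 3, seed = 5)$labels), 1)
  expect_equal(ari(m1$labels, fitModel(z3, 3, seed = 5)$labels), 1)
})

test_that("planted binding modes are recovered end to end", {
  spec <- syntheticSpec(n_modes = 3, mode_fractions = c(0.61, 0.23, 0.16),
                        mode_separation = 1.25, noise_sigma = 0.25,
                        n_frames = 400, seed = 17)
  g <- generateSystem(spec)
  res <- clusterBindingModes(g$trajectory,
                             contact_residues = syntheticContacts(spec),
                             seed = 71)
  expect_equal(as.integer(res$k), 3L)
  expect_gte(ari(res$model$labels, g$ground_truth$mode), 0.9)
  expect_equal(res$model$weights_pct, c(61, 23, 16), tolerance = 0.05)
})
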