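# outline resampling, Procrustes superimposition, group means

test_that("resampling places points at equal arc length", {
  seg <- rbind(c(0, 0), c(10, 0))
  out <- resamplePolyline(seg, 5)
  expect_equal(out[, 1], c(0, 2.5, 5, 7.5, 10))
  expect_equal(out[, 2], rep(0, 5))

  # right angle: total length 7, midpoint at arc length 3.5 -> (3, 0.5)
  elbow <- rbind(c(0, 0), c(3, 0), c(3, 4))
  out <- resamplePolyline(elbow, 3)
  expect_equal(out[2, ], c(3, 0.5), tolerance = 1e-12)
  expect_equal(out[1, ], c(0, 0))
  expect_equal(out[3, ], c(3, 4))
})

test_that("resampling agrees with a brute-force refinement oracle", {
  set.seed(11)
  curve <- cbind(cumsum(runif(6)), rnorm(6))
  n <- 9
  got <- resamplePolyline(curve, n)
  # oracle: walk a 1e5-point piecewise-linear refinement of the curve
  tgrid <- seq(0, 1, length.out = 1e5)
  fine <- cbind(approx(seq_len(6), curve[, 1], xout = 1 + tgrid * 5)$y,
                approx(seq_len(6), curve[, 2], xout = 1 + tgrid * 5)$y)
  seg <- sqrt(rowSums(diff(fine)^2))
  cum <- c(0, cumsum(seg))
  L <- sum(seg)
  idx <- sapply(seq(0, L, length.out = n), function(s)
    which.min(abs(cum - s)))
  expect_equal(got, fine[idx, ], tolerance = 1e-3)
})

test_that("resampling an equally spaced curve at its own count is identity", {
  curve <- cbind(seq(0, 1, length.out = 12), 0.5)
  expect_equal(resamplePolyline(curve, 12), curve, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_error(resamplePolyline(rbind(c(1, 1), c(1, 1)), 4),
               "zero-length")
})

test_that("specimens convert to configurations with configured counts", {
  r1 <- SpecimenRecord("a", "mandible",
                       curves = list(rbind(c(0, 0), c(10, 0))),
                       landmarks = rbind(c(0, 5)))
  r2 <- SpecimenRecord("b", "mandible",
                       curves = list(rbind(c(0, 0), c(5, 5))),
                       landmarks = rbind(c(1, 1)))
  got <- specimensToConfigs(list(r1, r2), resampleCounts = 4L)
  expect_equal(got$k, 5L)  # 4 semi-landmarks + 1 fixed landmark
  expect_identical(names(got$configs), c("a", "b"))
  # reverse flag flips the traversal direction
  rev <- specimensToConfigs(list(r1, r2), resampleCounts = 4L,
                            reverseCurves = TRUE)
  expect_equal(rev$configs[["a"]][1, ], c(10, 0))
})

test_that("exactly superimposable shapes end at Procrustes distance zero", {
  set.seed(3)
  tri <- randConfig(3)
  th <- pi / 2
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  tri2 <- 2 * tri %*% R + 1  # rotated 90 deg, scaled x2, translated
  al <- gpaAlign(list(a = tri, b = tri2))
  expect_true(al@converged)
  X <- alignedCoords(al)
  expect_lt(sqrt(sum((X[1, ] - X[2, ])^2)), 1e-10)
})

test_that("aligned configurations are centered with unit centroid size", {
  set.seed(4)
  al <- gpaAlign(lapply(1:6, function(i) randConfig(7)))
  X <- alignedCoords(al)
  for (i in seq_len(nrow(X))) {
    cfg <- matrix(X[i, ], ncol = 2, byrow = TRUE)
    expect_lt(max(abs(colMeans(cfg))), 1e-9)
    expect_lt(abs(sqrt(sum(cfg^2)) - 1), 1e-9)
  }
  # consensus is the mean of the aligned configurations (up to renorm)
  cons <- consensusShape(al)
  mean_cfg <- matrix(colMeans(X), ncol = 2, byrow = TRUE)
  mean_cfg <- mean_cfg / sqrt(sum(mean_cfg^2))
  expect_equal(cons, mean_cfg, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("GPA consensus matches an independent alternating-OPA oracle", {
  set.seed(5)
  quads <- lapply(1:5, function(i) randConfig(4))
  al <- gpaAlign(quads)
  oc <- oracleGPA(quads)
  # consensus defined up to rotation: compare by Procrustes distance
  expect_lt(procrustesDistance(consensusShape(al), oc), 1e-8)
})

test_that("GPA is a fixed point on already-aligned output", {
  set.seed(6)
  al <- gpaAlign(lapply(1:5, function(i) randConfig(6)))
  shapes <- lapply(seq_len(nrow(alignedCoords(al))), function(i)
    matrix(alignedCoords(al)[i, ], ncol = 2, byrow = TRUE))
  al2 <- gpaAlign(shapes)
  expect_lt(procrustesDistance(consensusShape(al2), consensusShape(al)),
            1e-10)
})

test_that("pairwise Procrustes distances ignore specimen input order", {
  set.seed(7)
  configs <- lapply(1:6, function(i) randConfig(5))
  names(configs) <- paste0("s", 1:6)
  d12 <- function(al, a, b) {
    X <- alignedCoords(al)
    procrustesDistance(matrix(X[a, ], ncol = 2, byrow = TRUE),
                       matrix(X[b, ], ncol = 2, byrow = TRUE))
  }
  al1 <- gpaAlign(configs)
  al2 <- gpaAlign(rev(configs))
  expect_equal(d12(al1, "s1", "s4"), d12(al2, "s1", "s4"),
               tolerance = 1e-8)
})

test_that("degenerate configurations are rejected", {
  expect_error(gpaAlign(list(randConfig(4))), "at least 2")
  flat <- matrix(1, 4, 2)  # all points identical: zero centroid size
  expect_error(gpaAlign(list(flat, randConfig(4))), "zero centroid size")
})

test_that("group mean shapes average tangent coordinates per group", {
  set.seed(8)
  base <- randConfig(6)
  configs <- c(lapply(1:2, function(i) base + 0.01 * randConfig(6)),
               lapply(1:3, function(i) 2 * base + 0.01 * randConfig(6)))
  names(configs) <- paste0("s", 1:5)
  al <- gpaAlign(configs)
  gt <- GroupTable(data.frame(
    specimen_id = paste0("s", 1:5),
    terminal_group = c("G1", "G1", "G2", "G2", "G2"),
    feeding_type = "omnivory"))
  ms <- groupMeanShapes(al, gt)
  X <- tangentCoords(al)
  manual <- matrix(colMeans(X[3:5, ]), ncol = 2, byrow = TRUE)
  expect_equal(nodeShape(ms, "G2"), manual, tolerance = 1e-12,
               ignore_attr = TRUE)
  # a singleton group's mean is that specimen's own shape
  gt1 <- GroupTable(data.frame(
    specimen_id = paste0("s", 1:5),
    terminal_group = c("solo", "G1", "G2", "G2", "G2"),
    feeding_type = "omnivory"))
  ms1 <- groupMeanShapes(al, gt1)
  expect_equal(nodeShape(ms1, "solo"),
               matrix(X[1, ], ncol = 2, byrow = TRUE),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("group means recover simulated tip means within the noise bound", {
  cfg <- simulationConfig(nTips = 4, treeType = "random",
                          characters = c(ch = 8L), noiseSd = 0.005,
                          nSpecimensPerTip = 20, baseRate = 1e-7,
                          seed = 99)
  ds <- simulateBMShapes(cfg)
  sc <- specimensToConfigs(ds$specimens$ch)
  al <- gpaAlign(sc$configs)
  ms <- groupMeanShapes(al, ds$groups)
  truth <- ds$truth$characters$ch$shapes
  bound <- 0.005 * (2 / sqrt(20)) * 3
  for (tp in ds$tree@phy$tip.label) {
    expect_lt(procrustesDistance(nodeShape(ms, tp),
                                 nodeShape(truth, tp)), bound)
  }
})
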