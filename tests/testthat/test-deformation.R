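# deformation ratios, SGR series, step charts, trend fits

# a CVAResult whose reduced space is the full space with identity W, so
# Mahalanobis degenerates to Euclidean
identityDistanceSpace <- function(p) {
  new("CVAResult", axes = diag(p)[, 1, drop = FALSE],
      centroids = matrix(0, 2, 1), W = diag(p), projection = diag(p),
      center = rep(0, p), groupMeans = matrix(0, 2, p),
      mahalanobis = matrix(0, 2, 2), euclidean = matrix(0, 2, 2),
      groups = c("g1", "g2"))
}

chainTree <- function() {
  # A -> B -> C lineage embedded in a rooted 2-tip tree is not possible;
  # use a 3-node ladder instead: root(10) -> mid(5) -> tip(0) plus a
  # second tip hanging off the root
  tinyTree("((A:5)m:5,B:10);", c(0, 0, 10, 5))
}

test_that("equal parent and child shapes give zero distance and DR", {
  tt <- balancedTimeTree(4, 20)
  x <- randConfig(5)
  shapes <- tipShapeSet(setNames(rep(list(x), 7), nodeLabels(tt)))
  ed <- edgeDeformations(tt, shapes, identityDistanceSpace(10))
  expect_equal(ed$d_euclidean, rep(0, 6))
  expect_equal(ed$dr_euclidean, rep(0, 6))
  expect_equal(ed$dr_mahalanobis, rep(0, 6))
})

test_that("DR is distance over elapsed time by definition", {
  phy <- ape::read.tree(text = "(A:2,B:2);")
  tt <- TimeTree(phy, ages = c(0, 0, 2))
  root <- randConfig(4)
  # place tip A exactly 4 Procrustes units from the root shape
  dirv <- randConfig(4)
  dirv <- dirv / sqrt(sum(dirv^2))
  shapes <- tipShapeSet(list(A = root + 4 * dirv, B = root,
                             Node1 = root))
  ed <- edgeDeformations(tt, shapes)
  rowA <- ed[ed$child == "A", ]
  expect_equal(rowA$d_euclidean, 4, tolerance = 1e-12)
  expect_equal(rowA$dt, 2)
  expect_equal(rowA$dr_euclidean, 2, tolerance = 1e-12)
  expect_true(all(is.na(ed$d_mahalanobis)))
})

test_that("identity pooled covariance makes both DR variants agree", {
  set.seed(31)
  tt <- balancedTimeTree(8, 100)
  tips <- setNames(lapply(1:8, function(i) randConfig(5)),
                   tt@phy$tip.label)
  rec <- reconstructShapes(tt, tips)
  ed <- edgeDeformations(tt, rec, identityDistanceSpace(10))
  expect_equal(ed$dr_mahalanobis, ed$dr_euclidean, tolerance = 1e-9)
})

test_that("non-positive elapsed time errors unless epsilon is requested", {
  phy <- ape::read.tree(text = "((A:0,B:1):1,C:2);")
  tt <- TimeTree(phy, ages = c(1, 0, 0, 2, 1))  # A is as old as its parent
  tips <- tipShapeSet(setNames(lapply(1:5, function(i) randConfig(4)),
                               nodeLabels(tt)))
  expect_error(edgeDeformations(tt, tips), "non-positive elapsed time")
  expect_warning(ed <- edgeDeformations(tt, tips,
                                        zeroLengthEdges = "epsilon"),
                 "zero-length")
  expect_true(all(ed$dt > 0))
})

test_that("SGR is the relative change between consecutive DRs", {
  tt <- chainTree()
  shapes <- tipShapeSet(setNames(lapply(1:4, function(i) randConfig(4)),
                                 nodeLabels(tt)))
  ed <- edgeDeformations(tt, shapes)
  # overwrite the Euclidean DRs with a known path: root->m 2, m->A 3
  ed$dr_euclidean[ed$child == "m"] <- 2
  ed$dr_euclidean[ed$child == "A"] <- 3
  sgr <- sgrAlongPaths(tt, ed, variant = "euclidean")
  expect_equal(sgr$sgr[sgr$path_id == "A"], 0.5)

  ed$dr_euclidean[ed$child == "m"] <- 1
  ed$dr_euclidean[ed$child == "A"] <- 1
  sgr <- sgrAlongPaths(tt, ed, variant = "euclidean")
  expect_equal(sgr$sgr[sgr$path_id == "A"], 0)
})

test_that("SGR matches the element-wise formula on random DR paths", {
  set.seed(32)
  # a 10-edge ladder: 9 nested internal nodes above tip A
  nest <- Reduce(function(acc, i) sprintf("(%s:1)n%d", acc, i),
                 2:10, accumulate = FALSE, init = "A:1")
  txt <- sprintf("(%s:1,B:10);", nest)
  phy <- ape::read.tree(text = txt)
  ages <- c(0, 0, 10:1)
  tt <- TimeTree(phy, ages)
  shapes <- tipShapeSet(setNames(lapply(seq_along(ages),
                                        function(i) randConfig(4)),
                                 nodeLabels(tt)))
  ed <- edgeDeformations(tt, shapes)
  dr <- runif(10, 0.1, 5)
  # the ladder path visits the edges in age order
  pathIdx <- order(-ed$parent_age)
  pathIdx <- pathIdx[ed$child[pathIdx] != "B"]
  ed$dr_euclidean[pathIdx] <- dr
  sgr <- sgrAlongPaths(tt, ed, variant = "euclidean")
  got <- sgr$sgr[sgr$path_id == "A"]
  expect_equal(got, diff(dr) / dr[-length(dr)], tolerance = 1e-12)
})

test_that("zero previous DR yields NA, never infinity", {
  tt <- chainTree()
  shapes <- tipShapeSet(setNames(lapply(1:4, function(i) randConfig(4)),
                                 nodeLabels(tt)))
  ed <- edgeDeformations(tt, shapes)
  ed$dr_euclidean[ed$child == "m"] <- 0
  expect_warning(sgr <- sgrAlongPaths(tt, ed, variant = "euclidean"),
                 "zero previous DR")
  expect_true(is.na(sgr$sgr[sgr$path_id == "A"]))
  expect_false(any(is.infinite(sgr$sgr)))
})

test_that("step series assign each edge's DR to its age interval", {
  phy <- ape::read.tree(text = "(A:10,B:10);")
  tt <- TimeTree(phy, ages = c(0, 0, 10))
  shapes <- tipShapeSet(setNames(lapply(1:3, function(i) randConfig(4)),
                                 nodeLabels(tt)))
  ed <- edgeDeformations(tt, shapes)
  ed$dr_euclidean <- c(0.3, 0.7)[match(ed$child, c("A", "B"))]
  st <- stepChartSeries(ed, tt, variant = "euclidean")
  expect_equal(nrow(st), 2L)  # one series per tip, each one edge
  expect_equal(st$age_start, c(10, 10))
  expect_equal(st$age_end, c(0, 0))
  expect_equal(sort(st$dr), c(0.3, 0.7))

  # ladder: 1 on [5,10], 2 on [0,5]
  tt2 <- chainTree()
  sh2 <- tipShapeSet(setNames(lapply(1:4, function(i) randConfig(4)),
                              nodeLabels(tt2)))
  ed2 <- edgeDeformations(tt2, sh2)
  ed2$dr_euclidean[ed2$child == "m"] <- 1
  ed2$dr_euclidean[ed2$child == "A"] <- 2
  st2 <- stepChartSeries(ed2, tt2, variant = "euclidean")
  stA <- st2[st2$lineage == "A", ]
  expect_equal(stA$dr[stA$age_start == 10 & stA$age_end == 5], 1)
  expect_equal(stA$dr[stA$age_start == 5 & stA$age_end == 0], 2)
})

test_that("step series cells join back to the edge table", {
  cfg <- simulationConfig(nTips = 8, characters = c(ch = 6L), seed = 5)
  ds <- simulateBMShapes(cfg)
  rec <- reconstructShapes(ds$tree, ds$truth$characters$ch$shapes)
  ed <- edgeDeformations(ds$tree, rec)
  st <- stepChartSeries(ed, ds$tree, variant = "euclidean")
  key <- paste(ed$parent, ed$child)
  for (i in seq_len(nrow(st))) {
    j <- match(paste(st$parent[i], st$child[i]), key)
    expect_equal(st$dr[i], ed$dr_euclidean[j])
    expect_equal(st$age_start[i], ed$parent_age[j])
    expect_equal(st$age_end[i], ed$child_age[j])
  }
})

test_that("rescaling time scales DR inversely and leaves SGR unchanged", {
  set.seed(33)
  cfg <- simulationConfig(nTips = 8, characters = c(ch = 8L), seed = 11)
  ds <- simulateBMShapes(cfg)
  tt <- ds$tree
  rec <- reconstructShapes(tt, ds$truth$characters$ch$shapes)
  ed1 <- edgeDeformations(tt, rec)
  c0 <- 3.7
  tt2 <- TimeTree(tt@phy, tt@ages * c0)
  ed2 <- edgeDeformations(tt2, rec)
  expect_equal(ed2$dr_euclidean, ed1$dr_euclidean / c0, tolerance = 1e-9)
  s1 <- sgrAlongPaths(tt, ed1, variant = "euclidean")
  s2 <- sgrAlongPaths(tt2, ed2, variant = "euclidean")
  expect_equal(s2$sgr, s1$sgr, tolerance = 1e-9)

  # scaling all distances leaves SGR unchanged too
  ed3 <- ed1
  for (cl in c("d_euclidean", "dr_euclidean")) ed3[[cl]] <- 5 * ed3[[cl]]
  s3 <- sgrAlongPaths(tt, ed3, variant = "euclidean")
  expect_equal(s3$sgr, s1$sgr, tolerance = 1e-9)
})

test_that("DR decreases with branch duration under constant-rate BM", {
  # longer branches accumulate displacement only as sqrt(t), so the rate
  # d/t should correlate negatively with t across edges
  set.seed(34)
  cfg <- simulationConfig(nTips = 16, treeType = "random",
                          characters = c(ch = 50L), baseRate = 1e-4,
                          noiseSd = 0, nSpecimensPerTip = 1, seed = 17)
  ds <- simulateBMShapes(cfg)
  rec <- reconstructShapes(ds$tree, ds$truth$characters$ch$shapes)
  ed <- edgeDeformations(ds$tree, rec)
  expect_lt(cor(ed$dr_euclidean, ed$dt, method = "spearman"), 0)
})

test_that("trend fits are exact on collinear and constant inputs", {
  pts <- data.frame(age = 1:10, value = 2 * (1:10) + 1)
  f <- fitTrend(pts, method = "ols_poly", degree = 1)
  expect_equal(unname(resid(f$model)), rep(0, 10), tolerance = 1e-10)
  expect_equal(f$coefficients, c(1, 2), tolerance = 1e-10)

  const <- data.frame(age = 1:8, value = 3)
  f2 <- fitTrend(const, method = "ols_poly", degree = 2)
  expect_equal(f2$grid$fitted, rep(3, nrow(f2$grid)), tolerance = 1e-10)
})

test_that("quadratic trend coefficients match the normal equations", {
  set.seed(35)
  age <- runif(20, 0, 100)
  y <- 0.5 - 0.02 * age + 3e-4 * age^2 + rnorm(20, sd = 0.05)
  f <- fitTrend(data.frame(age = age, value = y), method = "ols_poly",
                degree = 2)
  X <- cbind(1, age, age^2)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(f$coefficients, drop(beta), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("underdetermined trend fits are rejected", {
  expect_error(fitTrend(data.frame(age = 1:2, value = 1:2)),
               "at least 3")
  expect_error(fitTrend(data.frame(age = 1:3, value = 1:3), degree = 5),
               "fewer points")
})
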