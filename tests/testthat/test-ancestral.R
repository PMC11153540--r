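# ancestral shapes (squared-change parsimony) and discrete states

twoTipTree <- function(t1 = 1, t2 = 2) {
  # tips at different ages so the two branch durations differ
  phy <- ape::read.tree(text = "(A:1,B:2);")
  TimeTree(phy, ages = c(max(t1, t2) - t1, max(t1, t2) - t2,
                         max(t1, t2)))
}

test_that("two-tip root is the precision-weighted mean of the tips", {
  t1 <- 1; t2 <- 2
  tt <- twoTipTree(t1, t2)
  set.seed(21)
  x1 <- randConfig(4); x2 <- randConfig(4)
  rec <- reconstructShapes(tt, list(A = x1, B = x2))
  expected <- (x1 / t1 + x2 / t2) / (1 / t1 + 1 / t2)
  expect_equal(nodeShape(rec, "Node1"), expected, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("star tree with equal branches reconstructs the tip mean", {
  phy <- ape::read.tree(text = "(A:5,B:5,C:5,D:5);")
  tt <- TimeTree(phy, ages = c(0, 0, 0, 0, 5))
  set.seed(22)
  tips <- setNames(lapply(1:4, function(i) randConfig(5)),
                   c("A", "B", "C", "D"))
  rec <- reconstructShapes(tt, tips)
  expect_equal(nodeShape(rec, "Node1"), Reduce(`+`, tips) / 4,
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("identical tips propagate unchanged to every internal node", {
  tt <- balancedTimeTree(8, 100)
  x <- randConfig(6)
  tips <- setNames(rep(list(x), 8), tt@phy$tip.label)
  rec <- reconstructShapes(tt, tips)
  for (lab in nodeLabels(tt))
    expect_equal(nodeShape(rec, lab), x, tolerance = 1e-10,
                 ignore_attr = TRUE)
})

test_that("reconstruction is linear in the tip shapes", {
  set.seed(23)
  tt <- randomTimeTree(6, 80, seed = 5)
  tipsX <- setNames(lapply(1:6, function(i) randConfig(4)),
                    tt@phy$tip.label)
  tipsY <- setNames(lapply(1:6, function(i) randConfig(4)),
                    tt@phy$tip.label)
  a <- 0.7; b <- -1.3
  mix <- setNames(lapply(tt@phy$tip.label, function(tp)
    a * tipsX[[tp]] + b * tipsY[[tp]]), tt@phy$tip.label)
  rx <- reconstructShapes(tt, tipsX)
  ry <- reconstructShapes(tt, tipsY)
  rm <- reconstructShapes(tt, mix)
  for (lab in nodeLabels(tt))
    expect_equal(nodeShape(rm, lab),
                 a * nodeShape(rx, lab) + b * nodeShape(ry, lab),
                 tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("weighted reconstruction agrees with ML ancestral states", {
  # ape::ace under Brownian motion is an independent route to the same
  # point estimates
  set.seed(24)
  tt <- randomTimeTree(8, 50, seed = 9)
  x <- rnorm(8)
  names(x) <- tt@phy$tip.label
  tips <- setNames(lapply(tt@phy$tip.label, function(tp)
    matrix(c(x[tp], 0, 1, 0, 0, 1), ncol = 2, byrow = TRUE)),
    tt@phy$tip.label)
  rec <- reconstructShapes(tt, tips, weighting = "branch_length")
  phy <- tt@phy
  a <- ape::ace(x, phy, method = "ML", model = "BM")
  internal <- tt@phy$node.label
  for (i in seq_along(internal))
    expect_lt(abs(nodeShape(rec, internal[i])[1, 1] - a$ace[i]), 1e-6)
})

test_that("missing tip shapes are a validation error", {
  tt <- balancedTimeTree(4, 10)
  tips <- setNames(lapply(1:3, function(i) randConfig(3)),
                   tt@phy$tip.label[1:3])
  expect_error(reconstructShapes(tt, tips), "missing tip shape")
})

test_that("parsimony solves the textbook three-tip case", {
  tt <- tinyTree("((A:1,B:1):1,C:2);", c(0, 0, 0, 2, 1))
  rec <- fitchSankoff(tt, c(A = "0", B = "1", C = "0"))
  expect_equal(rec@treeLength, 1)
  expect_identical(rec@stateSets[["Node1"]], "0")
  # state 1 at the (A,B) ancestor would cost 2 changes, so it is excluded
  expect_identical(rec@stateSets[["Node2"]], "0")
})

test_that("uniform tip states give zero parsimony length everywhere", {
  tt <- balancedTimeTree(8, 100)
  st <- setNames(rep("omnivory", 8), tt@phy$tip.label)
  rec <- fitchSankoff(tt, st,
                      states = c("omnivory", "coprophagy", "phytophagy"))
  expect_equal(rec@treeLength, 0)
  for (lab in nodeLabels(tt))
    expect_identical(rec@stateSets[[lab]], "omnivory")
})

test_that("a cherry with differing states reports the Fitch union", {
  phy <- ape::read.tree(text = "(A:1,B:1);")
  tt <- TimeTree(phy, ages = c(0, 0, 1))
  rec <- fitchSankoff(tt, c(A = "0", B = "1"))
  expect_setequal(rec@stateSets[["Node1"]], c("0", "1"))
  expect_equal(rec@treeLength, 1)
})

test_that("parsimony matches exhaustive enumeration on random trees", {
  set.seed(25)
  for (rep in 1:12) {
    n <- sample(3:6, 1)
    phy <- ape::rtree(n)
    phy$edge.length <- rep(1, nrow(phy$edge))
    depth <- ape::node.depth.edgelength(phy)
    ages <- max(depth) - depth
    ages[seq_len(n)] <- pmax(ages[seq_len(n)], 0)
    tt <- TimeTree(phy, ages)
    states <- as.character(seq_len(sample(2:3, 1)))
    tipStates <- setNames(sample(states, n, replace = TRUE),
                          phy$tip.label)
    rec <- fitchSankoff(tt, tipStates, states = states)
    oracle <- oracleParsimony(phy, tipStates, states)
    expect_equal(rec@treeLength, oracle$length)
    labs <- nodeLabels(tt)
    for (j in seq_len(phy$Nnode))
      expect_setequal(rec@stateSets[[labs[n + j]]], oracle$sets[[j]])
  }
})

test_that("parsimony length is invariant under state relabeling", {
  set.seed(26)
  tt <- randomTimeTree(8, 60, seed = 4)
  states <- c("x", "y", "z")
  tipStates <- setNames(sample(states, 8, replace = TRUE),
                        tt@phy$tip.label)
  base <- fitchSankoff(tt, tipStates, states = states)
  perm <- setNames(c("z", "x", "y"), states)
  rec2 <- fitchSankoff(tt, setNames(unname(perm[tipStates]),
                                    names(tipStates)),
                       states = unname(perm[states]))
  expect_equal(rec2@treeLength, base@treeLength)
})

test_that("parsimony length agrees with phangorn on larger trees", {
  set.seed(27)
  tt <- randomTimeTree(12, 100, seed = 8)
  states <- c("a", "b", "c")
  tipStates <- setNames(sample(states, 12, replace = TRUE),
                        tt@phy$tip.label)
  rec <- fitchSankoff(tt, tipStates, states = states)
  dat <- phangorn::phyDat(matrix(tipStates, ncol = 1,
                                 dimnames = list(names(tipStates), NULL)),
                          type = "USER", levels = states)
  expect_equal(rec@treeLength,
               phangorn::parsimony(tt@phy, dat, method = "sankoff"))
})

test_that("near-zero rate concentrates Mk weights on the shared state", {
  phy <- ape::read.tree(text = "(A:10,B:10);")
  tt <- TimeTree(phy, ages = c(0, 0, 10))
  rec <- mkMLStates(tt, c(A = "s1", B = "s1"), states = c("s1", "s2"),
                    rate = 1e-9)
  expect_gt(rec@weights["Node1", "s1"], 1 - 1e-6)
})

test_that("Mk marginals match the exhaustive-sum oracle at fixed rate", {
  tt <- tinyTree("((A:30,B:30):40,(C:50,D:50):20);",
                 c(0, 0, 0, 0, 70, 30, 50))
  states <- c("omnivory", "coprophagy", "phytophagy")
  tipStates <- c(A = "omnivory", B = "coprophagy", C = "phytophagy",
                 D = "phytophagy")
  rec <- mkMLStates(tt, tipStates, states = states, rate = 0.01)
  oracle <- oracleMkMarginals(tt@phy, tt@ages, tipStates, states, 0.01)
  labs <- nodeLabels(tt)
  for (i in seq_along(labs))
    expect_equal(unname(rec@weights[labs[i], ]), unname(oracle[i, ]),
                 tolerance = 1e-10)
})

test_that("Mk rate optimization recovers a sensible rate and weights sum to 1", {
  set.seed(28)
  tt <- randomTimeTree(16, 150, seed = 13)
  sim <- simulateDiscreteTrait(tt, c("a", "b", "c"), rate = 0.01,
                               seed = 3)
  rec <- mkMLStates(tt, sim$tipStates)
  expect_true(all(abs(rowSums(rec@weights) - 1) < 1e-9))
  expect_gt(rec@rate, 0)
  # tip weights are indicators of the observed states
  for (tp in tt@phy$tip.label)
    expect_equal(unname(rec@weights[tp, sim$tipStates[[tp]]]), 1,
                 tolerance = 1e-9)
})

test_that("states outside the vocabulary are rejected", {
  tt <- balancedTimeTree(4, 10)
  st <- setNames(c("a", "b", "q", "a"), tt@phy$tip.label)
  expect_error(fitchSankoff(tt, st, states = c("a", "b")), "vocabulary")
  expect_error(mkMLStates(tt, st, states = c("a", "b")), "vocabulary")
})
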