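test_that("nodal strength sums incident weights", {
  expect_equal(unname(nodalStrength(chainConnectome())), c(1, 5, 4))
  withr::local_seed(61)
  conn <- randomConnectome(15)
  s <- nodalStrength(conn)
  w <- connWeights(conn)
  expect_equal(sum(s), 2 * sum(w[upper.tri(w)]), tolerance = 1e-12)
  expect_equal(unname(s), unname(apply(w, 1, sum)), tolerance = 1e-12)
})

test_that("Onnela clustering matches triple enumeration and stays in [0, 1]", {
  expect_equal(unname(clusteringCoefficient(completeConnectome(3))), rep(1, 3))
  expect_equal(unname(clusteringCoefficient(starConnectome(4))), rep(0, 5))
  withr::local_seed(67)
  for (trial in 1:5) {
    conn <- randomConnectome(sample(4:7, 1))
    cc <- clusteringCoefficient(conn)
    expect_equal(unname(cc), bruteOnnela(connWeights(conn)), tolerance = 1e-12)
    expect_true(all(cc >= 0 & cc <= 1))
  }
})

test_that("betweenness matches exhaustive path enumeration", {
  # path graph: only the middle node lies between others
  w <- matrix(0, 3, 3); w[1, 2] <- w[2, 1] <- 1; w[2, 3] <- w[3, 2] <- 1
  expect_equal(unname(betweennessCentrality(WeightedConnectome(w))), c(0, 1, 0))
  expect_equal(unname(betweennessCentrality(completeConnectome(5))), rep(0, 5))
  withr::local_seed(71)
  for (trial in 1:4) {
    conn <- randomConnectome(sample(5:8, 1))
    len <- edgeLengths(conn)
    expect_equal(unname(betweennessCentrality(conn)), bruteBetweenness(len),
                 tolerance = 1e-9)
  }
  # invariant under uniform weight scaling
  conn <- randomConnectome(10)
  scaled <- WeightedConnectome(connWeights(conn) * 4.2, nodeLabels(conn))
  expect_equal(betweennessCentrality(scaled), betweennessCentrality(conn),
               tolerance = 1e-9)
})

test_that("embeddedness proxy respects symmetry and hub dominance", {
  # cycle: vertex-transitive, all scores equal
  n <- 8
  w <- matrix(0, n, n)
  for (i in seq_len(n)) { j <- if (i == n) 1 else i + 1; w[i, j] <- w[j, i] <- 2 }
  sc <- embeddednessScore(WeightedConnectome(w))
  expect_equal(max(sc) - min(sc), 0, tolerance = 1e-9)
  # weighted star: the hub sees every node in one hop, so its decay rate is
  # undefined and it carries the documented +Inf marker, ranking above the
  # leaves, whose shell profile decays and yields finite scores
  star <- starConnectome(6, hubWeight = 5)
  expect_warning(sc2 <- embeddednessScore(star), "non-decaying")
  expect_true(is.infinite(sc2["hub"]))
  expect_true(all(is.finite(sc2[-1])))
  expect_true(all(sc2["hub"] > sc2[-1]))
  # single-shell nodes (complete graph) degenerate to Inf with a warning
  expect_warning(sc3 <- embeddednessScore(completeConnectome(4)),
                 "non-decaying")
  expect_true(all(is.infinite(sc3)))
  # user-supplied ranking passes through unchanged
  r <- seq_len(7) * 1.5
  expect_equal(unname(embeddednessScore(star, ranking = r)), r)
})

test_that("centrality validation returns exact fits and detects decorrelation", {
  # mirrored pairs at radius 2 * npl + 1: centroid at the origin, so the
  # centre distance is exactly linear in npl
  vals <- seq(1, 3, length.out = 25)
  npl <- rep(vals, each = 2)
  coords <- cbind(rep(c(1, -1), 25) * (2 * npl + 1), 0, 0)
  v <- centralityValidation(coords, npl, "toy")
  expect_equal(v$rSquared, 1, tolerance = 1e-12)
  expect_equal(v$rmse, 0, tolerance = 1e-9)
  withr::local_seed(73)
  syn <- makeModularConnectome(n = 200, seed = 1)
  npl2 <- nodalPathLength(graphDistances(syn$connectome))
  perm <- sample(200)
  v2 <- centralityValidation(as.matrix(syn$nodes[, c("x", "y", "z")]),
                             npl2[perm], "shuffled")
  expect_lt(v2$rSquared, 0.1)
  expect_error(centralityValidation(matrix(1, 10, 3), seq_len(10)),
               "degenerate")
})

test_that("centrality validation is invariant under rigid motion", {
  withr::local_seed(79)
  coords <- matrix(rnorm(60), 20, 3)
  npl <- rnorm(20)
  v1 <- centralityValidation(coords, npl)
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  v2 <- centralityValidation(sweep(coords %*% q, 2, c(5, -3, 11), `+`), npl)
  expect_equal(v1$rSquared, v2$rSquared, tolerance = 1e-9)
})

test_that("centre-distance ranking sorts ascending with label tie-breaks", {
  co <- rbind(c(2, 0, 0), c(1, 0, 0), c(3, 0, 0), c(-6, 0, 0))
  co <- sweep(co, 2, colMeans(co))
  e <- new("ConnectomeEmbedding", coords = co, method = "MDS",
           kUsed = NA_integer_, eigenvalues = c(3, 0, 0))
  rownames(e@coords) <- c("n2", "n1", "n3", "far")
  rk <- rankByCenterDistance(e)
  expect_equal(rk$label, c("n1", "n2", "n3", "far"))
  expect_equal(rk$rank, 1:4)
  # exact ties fall back to alphabetical order
  co2 <- rbind(c(1, 0), c(-1, 0), c(1, 0), c(-1, 0))
  e2 <- new("ConnectomeEmbedding", coords = co2, method = "MDS",
            kUsed = NA_integer_, eigenvalues = c(4, 0))
  rownames(e2@coords) <- c("d", "b", "a", "c")
  expect_equal(rankByCenterDistance(e2)$label, c("a", "b", "c", "d"))
})

test_that("dimension sweep returns aligned non-negative errors that improve by d = 3", {
  syn <- makeModularConnectome(n = 100, seed = 2)
  gd <- graphDistances(syn$connectome)
  sw <- dimensionSweep(highDimRepresentation(gd), nodalPathLength(gd),
                       dims = c(1, 3, 5))
  expect_equal(sw$dims, c(1L, 3L, 5L))
  expect_length(sw$rmse, 3)
  expect_true(all(sw$rmse >= 0))
  expect_true(all(sw$kUsed >= 3))
  expect_lt(sw$rmse[2], sw$rmse[1])
})
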