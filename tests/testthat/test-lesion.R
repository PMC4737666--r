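test_that("node removal is a pure submatrix and guards connectivity", {
  star <- starConnectome(3)
  surv <- removeNodes(star, "leaf3")
  expect_equal(nNodes(surv), 3)
  expect_equal(connWeights(surv),
               connWeights(star)[c("hub", "leaf1", "leaf2"),
                                 c("hub", "leaf1", "leaf2")])
  expect_error(removeNodes(star, "hub"), "disconnects")
  expect_error(removeNodes(star, c("hub", "leaf1", "leaf2", "leaf3")),
               "proper subset")
  expect_error(removeNodes(star, "nope"), "unknown node")
})

test_that("removing 21.5% of 620 nodes leaves 487 survivors", {
  # ring plus an all-to-hub star: survives any removal that spares the hub
  n <- 620
  w <- matrix(0, n, n)
  idx <- cbind(seq_len(n), c(seq_len(n)[-1], 1))
  w[idx] <- 1; w[idx[, 2:1]] <- 1
  w[, 1] <- w[1, ] <- 2; diag(w) <- 0
  conn <- WeightedConnectome(w)
  nRemove <- intrinsicConnectome:::roundHalfUp(0.215 * n)
  expect_equal(nRemove, 133)
  withr::local_seed(83)
  repeat {
    drawn <- sample(nodeLabels(conn), nRemove)
    surv <- tryCatch(removeNodes(conn, drawn), error = function(e) NULL)
    if (!is.null(surv)) break
  }
  expect_equal(nNodes(surv), 487)
})

test_that("d-bar is the mean centre distance, homogeneous under scaling", {
  theta <- seq(0, 2 * pi, length.out = 9)[-9]
  co <- cbind(cos(theta), sin(theta))
  e <- new("ConnectomeEmbedding", coords = co, method = "MDS",
           kUsed = NA_integer_, eigenvalues = c(1, 1))
  expect_equal(dbar(e), 1, tolerance = 1e-12)
  e2 <- e; e2@coords <- co * 3.5
  expect_equal(dbar(e2), 3.5, tolerance = 1e-12)
  withr::local_seed(89)
  co3 <- scale(matrix(rnorm(60), 20, 3), scale = FALSE)
  e3 <- new("ConnectomeEmbedding", coords = co3, method = "Isomap",
            kUsed = 3L, eigenvalues = c(3, 2, 1))
  expect_equal(dbar(e3), mean(sqrt(rowSums(co3^2))), tolerance = 1e-12)
  # invariant under orthogonal maps
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  e4 <- e3; e4@coords <- co3 %*% q
  expect_equal(dbar(e4), dbar(e3), tolerance = 1e-12)
})

test_that("normalized d-bar multiplies by the surviving mean weight", {
  conn <- completeConnectome(4, weight = 3)
  expect_equal(normalizedDbar(2, conn), 6)
  # multiplier 1: all-pairs mean of a complete unit-weight graph
  expect_equal(normalizedDbar(1.23, completeConnectome(5, 1)), 1.23)
  # zeros count toward the all-pairs mean unless switched off
  conn2 <- chainConnectome()
  expect_equal(normalizedDbar(1, conn2), mean(c(1, 4, 0)))
  expect_equal(normalizedDbar(1, conn2, includeZeros = FALSE), 2.5)
})

test_that("targeted schemes remove exactly the independently ranked nodes", {
  syn <- makeModularConnectome(n = 80, seed = 6)
  conn <- syn$connectome
  labels <- nodeLabels(conn)
  gd <- graphDistances(conn)
  nRemove <- intrinsicConnectome:::roundHalfUp(0.215 * 80)
  expected <- list(
    strength = labels[order(-nodalStrength(conn), labels)][1:nRemove],
    clustering = labels[order(clusteringCoefficient(conn), labels)][1:nRemove],
    path_length = labels[order(nodalPathLength(gd), labels)][1:nRemove],
    betweenness = labels[order(-betweennessCentrality(conn), labels)][1:nRemove])
  for (scheme in names(expected)) {
    res <- targetedRemoval(conn, scheme, 0.215, embedDim = 3)
    expect_setequal(res@removed, expected[[scheme]])
    expect_equal(length(res@removed), nRemove)
    expect_gte(res@dbarRaw, 0)
    expect_gte(res@dbarNormalized, 0)
  }
  # rich-club scheme removes exactly the flagged set
  rc <- targetedRemoval(conn, "rich_club", nodes = syn$nodes)
  expect_setequal(rc@removed, syn$nodes$label[syn$nodes$rich_club])
  expect_error(targetedRemoval(conn, "rich_club"), "rich_club")
  expect_error(targetedRemoval(conn, "no_such_scheme", 0.2), "unknown scheme")
})

test_that("custom rankings drive removal order", {
  syn <- makeModularConnectome(n = 40, seed = 8)
  conn <- syn$connectome
  r <- seq_len(40)   # highest score = node 40
  res <- targetedRemoval(conn, "custom", fraction = 0.1, ranking = r)
  expect_setequal(res@removed, nodeLabels(conn)[37:40])
})

test_that("random removal distributions are reproducible and well-formed", {
  syn <- makeModularConnectome(n = 80, seed = 9)
  conn <- syn$connectome
  a <- randomRemovalDistribution(conn, 0.2, trials = 8, seed = 100)
  b <- randomRemovalDistribution(conn, 0.2, trials = 8, seed = 100)
  expect_identical(a@dbarValues, b@dbarValues)
  expect_equal(a@mean, mean(a@dbarValues))
  expect_true(a@interval[1] <= a@mean && a@mean <= a@interval[2])
  one <- randomRemovalDistribution(conn, 0.2, trials = 1, seed = 5)
  expect_equal(one@interval, rep(one@mean, 2))
})

test_that("Monte-Carlo means are stable across seeds", {
  syn <- makeModularConnectome(n = 60, seed = 10)
  conn <- syn$connectome
  a <- randomRemovalDistribution(conn, 0.2, trials = 40, seed = 1)
  b <- randomRemovalDistribution(conn, 0.2, trials = 40, seed = 2)
  se <- sqrt(sd(a@dbarValues)^2 / 40 + sd(b@dbarValues)^2 / 40)
  expect_lt(abs(a@mean - b@mean), 3 * se)
})

test_that("fragile networks exhaust the redraw budget with a clear error", {
  n <- 20
  w <- matrix(0, n, n)
  for (i in seq_len(n - 1)) w[i, i + 1] <- w[i + 1, i] <- 1
  path <- WeightedConnectome(w)
  expect_error(randomRemovalDistribution(path, 0.5, trials = 2, seed = 3),
               "too fragile")
})
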