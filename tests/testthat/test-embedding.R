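test_that("classical MDS recovers simple geometries exactly", {
  # two points at distance 3 -> +-1.5 on one axis
  e <- classicalMDS(matrix(c(0, 3, 3, 0), 2), 1)
  expect_equal(sort(as.vector(embeddingCoords(e))), c(-1.5, 1.5))
  # unit square recovered up to rotation/reflection
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  e2 <- classicalMDS(as.matrix(dist(sq)), 2)
  expect_lt(procrustesError(sq, embeddingCoords(e2)), 1e-8)
  # intrinsically 2-D input: third eigenvalue vanishes
  e3 <- classicalMDS(as.matrix(dist(sq)), 3)
  ev <- embeddingEigenvalues(e3)
  expect_lt(ev[3], 1e-8 * ev[1])
  expect_error(classicalMDS(as.matrix(dist(sq)), 4), "n - 1")
})

test_that("classical MDS agrees with stats::cmdscale on random clouds", {
  withr::local_seed(23)
  x <- matrix(rnorm(40 * 4), 40, 4)
  dm <- as.matrix(dist(x))
  mine <- embeddingCoords(classicalMDS(dm, 3))
  ref <- cmdscale(dm, k = 3)
  expect_lt(procrustesError(ref, mine), 1e-8)
})

test_that("MDS recovers random point clouds at their true dimension", {
  withr::local_seed(29)
  for (p in 2:4) {
    x <- matrix(rnorm(30 * p), 30, p)
    e <- classicalMDS(as.matrix(dist(x)), p)
    expect_lt(procrustesError(x, embeddingCoords(e)), 1e-8)
  }
})

test_that("embedding output is centred, deterministic in sign, eigenvalues sorted", {
  withr::local_seed(31)
  x <- matrix(rnorm(25 * 5), 25, 5)
  e <- classicalMDS(as.matrix(dist(x)), 3)
  co <- embeddingCoords(e)
  expect_lt(max(abs(colMeans(co))), 1e-9)
  expect_false(is.unsorted(rev(embeddingEigenvalues(e))))
  for (j in 1:3) expect_gt(co[which.max(abs(co[, j])), j], 0)
  # identical rerun gives identical coordinates
  expect_identical(co, embeddingCoords(classicalMDS(as.matrix(dist(x)), 3)))
})

test_that("minConnectedK finds the smallest connecting neighbourhood", {
  # three collinear equidistant points connect at k = 1 under union symmetrization
  expect_equal(minConnectedK(cbind(c(0, 1, 2), 0), 1), 1L)
  expect_equal(minConnectedK(cbind(c(0, 5), 0), 1), 1L)
  # two tight clusters: returned k bridges them, k - 1 does not
  withr::local_seed(37)
  pts <- rbind(matrix(rnorm(10, 0, 0.1), 5, 2),
               matrix(rnorm(10, 50, 0.1), 5, 2))
  k <- minConnectedK(pts, 1)
  expect_gt(k, 1)
  dm <- as.matrix(dist(pts))
  connected <- function(kk) {
    adj <- matrix(FALSE, 10, 10)
    for (i in 1:10) {
      nb <- setdiff(order(dm[i, ]), i)[seq_len(kk)]
      adj[i, nb] <- TRUE
    }
    g <- igraph::graph_from_adjacency_matrix(adj | t(adj), "undirected")
    igraph::is_connected(g)
  }
  expect_true(connected(k))
  expect_false(connected(k - 1))
})

test_that("Isomap at full k coincides with classical MDS on ambient distances", {
  withr::local_seed(41)
  x <- matrix(rnorm(20 * 3), 20, 3)
  iso <- isomapEmbed(x, 2, k = 19)
  mds <- classicalMDS(as.matrix(dist(x)), 2)
  expect_lt(procrustesError(embeddingCoords(mds), embeddingCoords(iso)), 1e-8)
})

test_that("Isomap AUTO records the minimal connecting k and rejects bad explicit k", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  iso <- isomapEmbed(sq, 2, k = "auto", kStart = 1)
  expect_equal(kUsed(iso), minConnectedK(sq, 1))
  withr::local_seed(43)
  pts <- rbind(matrix(rnorm(10, 0, 0.1), 5, 2),
               matrix(rnorm(10, 50, 0.1), 5, 2))
  expect_error(isomapEmbed(pts, 2, k = 2), "auto")
})

test_that("Isomap agrees with vegan's implementation on a small cloud", {
  withr::local_seed(47)
  x <- matrix(rnorm(40 * 3), 40, 3)
  k <- minConnectedK(x, 3)
  mine <- isomapEmbed(x, 2, k = k)
  ref <- vegan::isomap(dist(x), ndim = 2, k = k)
  expect_lt(procrustesError(vegan::scores(ref), embeddingCoords(mine)), 1e-6)
})

test_that("Isomap unrolls a Swiss roll where MDS cannot", {
  roll <- makeSwissRoll(400, 0, seed = 1)
  iso <- isomapEmbed(roll$ambient, 2)
  mds <- classicalMDS(as.matrix(dist(roll$ambient)), 2)
  trueD <- as.vector(dist(roll$intrinsic))
  r2 <- function(e) cor(trueD, as.vector(dist(embeddingCoords(e))))^2
  expect_gt(r2(iso), 0.95)
  expect_gt(r2(iso), r2(mds))
})

test_that("distance to centre is a centred norm, invariant under rotation", {
  e <- classicalMDS(matrix(c(0, 2, 2, 0), 2), 1)
  expect_equal(unname(distanceToCenter(e)), c(1, 1))
  withr::local_seed(53)
  x <- rbind(matrix(rnorm(20, 0, 0.5), 10, 2), c(20, 20))
  dc <- distanceToCenter(x)
  expect_equal(which.max(dc), 11L)
  theta <- runif(1, 0, 2 * pi)
  rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  expect_equal(distanceToCenter(x %*% rot), dc, tolerance = 1e-9)
})

test_that("residual variance is 0 for perfect fits and near 1 for noise", {
  withr::local_seed(59)
  x <- matrix(rnorm(30 * 2), 30, 2)
  dm <- as.matrix(dist(x))
  e <- classicalMDS(dm, 2)
  expect_lt(residualVariance(dm, e), 1e-12)
  # scrambled distances decorrelate
  perm <- sample(30)
  expect_gt(residualVariance(dm[perm, perm], e), 0.9)
  const <- matrix(1, 30, 30) - diag(30)
  expect_error(residualVariance(const, e), "degenerate")
})

test_that("residual variance is non-increasing in embedding dimension", {
  syn <- makeModularConnectome(n = 60, seed = 4)
  rep_ <- highDimRepresentation(graphDistances(syn$connectome))
  dm <- as.matrix(dist(rep_))
  rv <- vapply(1:6, function(d) residualVariance(dm, classicalMDS(dm, d)),
               numeric(1))
  expect_true(all(diff(rv) <= 1e-10))
})
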