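# Fixtures and independent oracles used across the suite.

# chain A-B (weight 1), B-C (weight 4)
chainConnectome <- function() {
  w <- matrix(0, 3, 3, dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  w["A", "B"] <- w["B", "A"] <- 1
  w["B", "C"] <- w["C", "B"] <- 4
  WeightedConnectome(w)
}

starConnectome <- function(nLeaves = 4, hubWeight = 1) {
  n <- nLeaves + 1
  w <- matrix(0, n, n)
  w[1, 2:n] <- w[2:n, 1] <- hubWeight
  WeightedConnectome(w, c("hub", paste0("leaf", seq_len(nLeaves))))
}

completeConnectome <- function(n, weight = 1) {
  w <- matrix(weight, n, n)
  diag(w) <- 0
  WeightedConnectome(w)
}

# random connected weighted connectome: ring backbone + random chords
randomConnectome <- function(n, pExtra = 0.3) {
  w <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    w[i, j] <- w[j, i] <- runif(1, 0.5, 5)
  }
  extra <- which(upper.tri(w) & w == 0, arr.ind = TRUE)
  keep <- runif(nrow(extra)) < pExtra
  for (r in which(keep)) {
    v <- runif(1, 0.5, 5)
    w[extra[r, 1], extra[r, 2]] <- w[extra[r, 2], extra[r, 1]] <- v
  }
  WeightedConnectome(w)
}

# independent all-pairs shortest-path oracle
floydWarshall <- function(len) {
  n <- nrow(len)
  d <- len
  for (k in seq_len(n)) {
    d <- pmin(d, outer(d[, k], d[k, ], `+`))
  }
  d
}

# optimal alignment residual of two configurations (orthogonal Procrustes
# with translation and scaling-free comparison)
procrustesError <- function(x, y) {
  x <- scale(x, scale = FALSE)
  y <- scale(y, scale = FALSE)
  s <- svd(crossprod(y, x))
  rot <- s$u %*% t(s$v)
  sqrt(sum((x - y %*% rot)^2) / nrow(x))
}

# brute-force node betweenness by enumerating all simple paths (small n);
# endpoints excluded, equal-length multiplicity split fractionally
bruteBetweenness <- function(len, tol = 1e-12) {
  n <- nrow(len)
  bt <- numeric(n)
  allPaths <- function(from, to, visited, acc) {
    if (from == to) return(list(acc))
    out <- list()
    for (nxt in seq_len(n)) {
      if (!visited[nxt] && is.finite(len[from, nxt])) {
        v2 <- visited; v2[nxt] <- TRUE
        out <- c(out, allPaths(nxt, to, v2, c(acc, nxt)))
      }
    }
    out
  }
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    visited <- rep(FALSE, n); visited[s] <- TRUE
    paths <- allPaths(s, t, visited, s)
    lens <- vapply(paths, function(p)
      sum(len[cbind(p[-length(p)], p[-1])]), numeric(1))
    best <- min(lens)
    sel <- which(lens <= best + tol)
    for (p in paths[sel]) {
      inner <- p[-c(1, length(p))]
      bt[inner] <- bt[inner] + 1 / length(sel)
    }
  }
  bt
}

# brute-force Onnela weighted clustering by triple enumeration
bruteOnnela <- function(w) {
  n <- nrow(w)
  wn <- (w / max(w))^(1 / 3)
  out <- numeric(n)
  for (i in seq_len(n)) {
    k <- sum(w[i, ] > 0)
    if (k < 2) next
    acc <- 0
    for (j in seq_len(n)) for (h in seq_len(n)) {
      if (j != i && h != i && j != h)
        acc <- acc + wn[i, j] * wn[i, h] * wn[j, h]
    }
    out[i] <- acc / (k * (k - 1))
  }
  out
}
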