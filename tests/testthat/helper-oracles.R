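# Independent brute-force oracles used against the compiled implementations.
# They deliberately share no code with the package internals: plain R,
# array-scan Dijkstra (no heap), explicit neighbour enumeration.

oracle_offsets <- function(conn) {
  g <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  g <- g[rowSums(g != 0) > 0, , drop = FALSE]
  if (conn == 6) g <- g[rowSums(abs(g)) == 1, , drop = FALSE]
  g
}

# naive single/multi-source Dijkstra over a voxel grid; step_cost(u, v)
# gives the edge weight between linear (1-based) indices
oracle_dijkstra <- function(dims, sources, step_cost, conn = 26) {
  n <- prod(dims)
  offs <- oracle_offsets(conn)
  dist <- rep(Inf, n)
  dist[sources] <- 0
  done <- rep(FALSE, n)
  idx_of <- function(i, j, k) i + dims[1] * (j + dims[2] * k) + 1
  for (iter in seq_len(n)) {
    cand <- which(!done & is.finite(dist))
    if (!length(cand)) break
    u <- cand[which.min(dist[cand])]
    done[u] <- TRUE
    u0 <- u - 1
    ui <- u0 %% dims[1]
    uj <- (u0 %/% dims[1]) %% dims[2]
    uk <- u0 %/% (dims[1] * dims[2])
    for (t in seq_len(nrow(offs))) {
      vi <- ui + offs[t, 1]; vj <- uj + offs[t, 2]; vk <- uk + offs[t, 3]
      if (vi < 0 || vi >= dims[1] || vj < 0 || vj >= dims[2] ||
          vk < 0 || vk >= dims[3]) next
      v <- idx_of(vi, vj, vk)
      nd <- dist[u] + step_cost(u, v)
      if (nd < dist[v]) dist[v] <- nd
    }
  }
  dist
}

# oracle for the centerline stage: cost of the optimal vesselness-weighted
# path between two voxels (physical edge lengths, weight floor)
oracle_path_cost <- function(V, dims, spacing, src, dst, conn = 26,
                             wfloor = 1e-6) {
  coords <- function(u) {
    u0 <- u - 1
    c(u0 %% dims[1], (u0 %/% dims[1]) %% dims[2], u0 %/% (dims[1] * dims[2]))
  }
  step_cost <- function(u, v) {
    w <- max(wfloor, 1 - (V[u] + V[v]) / 2)
    w * sqrt(sum(((coords(u) - coords(v)) * spacing)^2))
  }
  oracle_dijkstra(dims, src, step_cost, conn)[dst]
}

# oracle for the lumen stage: per-voxel exhaustive classification -- for
# every undetermined voxel run its own single-source Dijkstra and take the
# minimum over each seed class (ties to label 1)
oracle_propagate <- function(I, dims, labels, conn = 26) {
  step_cost <- function(u, v) abs(I[u] - I[v])
  s1 <- which(labels == 1L)
  s2 <- which(labels == 2L)
  out <- labels
  mincost <- rep(0, length(labels))
  for (p in which(labels == 0L)) {
    dist <- oracle_dijkstra(dims, p, step_cost, conn)
    d1 <- min(dist[s1]); d2 <- min(dist[s2])
    out[p] <- if (d1 <= d2) 1L else 2L
    mincost[p] <- min(d1, d2)
  }
  list(labels = out, cost = mincost)
}

# SeedLabelMap from a raw {0,1,2} label array
make_seed_map <- function(lab, spacing = c(1, 1, 1)) {
  lab <- array(as.integer(lab), dim(lab))
  counts <- tabulate(lab + 1L, nbins = 3L)
  new("SeedLabelMap", labels = lab,
      counts = c(`0` = counts[1], `1` = counts[2], `2` = counts[3]),
      spacing = spacing, origin = c(0, 0, 0), direction = diag(3))
}

# simple straight-duct phantom spec used by several tests
straight_spec <- function(radius = 2, shape = c(24L, 24L, 30L),
                          axis_xy = c(12.3, 11.6), seed = 11L) {
  new("PhantomSpec", shape = shape, spacing = c(1, 1, 1),
      ductPath = rbind(c(axis_xy, 5), c(axis_xy, shape[3] - 6)),
      ductRadius = radius, intensityBackground = -50,
      intensityParenchyma = 90, intensityDuct = 15,
      parenchymaMargin = 2, noiseSigma = 0, blurSigmaMm = 0,
      seed = as.integer(seed))
}
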