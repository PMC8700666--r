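# Shared fixtures and brute-force oracles, all built in code.

fixture_cache <- new.env(parent = emptyenv())

# cached phantom per (condition, seed): generation is a few seconds each
cached_phantom <- function(condition, seed = 1L, shape = 112L) {
  key <- paste(condition, seed, shape, sep = "_")
  if (is.null(fixture_cache[[key]]))
    fixture_cache[[key]] <- generate_phantom(
      phantom_preset(condition, shape = rep(shape, 3), seed = seed))
  fixture_cache[[key]]
}

# digitized ball mask: voxel centres within `radius` of `center`
ball_mask <- function(n, center, radius) {
  co <- as.matrix(expand.grid(y = 1:n, x = 1:n, z = 1:n))
  array(rowSums(sweep(co, 2, center)^2) <= radius^2, c(n, n, n))
}

# brute-force squared EDT: min squared distance to any background voxel
brute_sqedt <- function(mask) {
  d <- dim(mask)
  co <- as.matrix(expand.grid(1:d[1], 1:d[2], 1:d[3]))
  bg <- co[!as.vector(mask), , drop = FALSE]
  if (!nrow(bg)) return(array(Inf, d))
  out <- vapply(seq_len(nrow(co)), function(i) {
    min(rowSums(sweep(bg, 2, co[i, ])^2))
  }, numeric(1))
  array(out, d)
}

# exhaustive local thickness oracle: test every foreground sphere centre,
# take the max diameter among spheres covering each voxel
brute_thickness <- function(mask) {
  d <- dim(mask)
  d2 <- brute_sqedt(mask)
  co <- as.matrix(expand.grid(1:d[1], 1:d[2], 1:d[3]))
  fg <- which(as.vector(mask))
  out <- numeric(prod(d))
  for (v in fg) {
    dist2 <- rowSums(sweep(co[fg, , drop = FALSE], 2, co[v, ])^2)
    cov <- dist2 < d2[fg]
    out[v] <- 2 * sqrt(max(d2[fg][cov]))
  }
  array(out, d)
}

# brute-force dilation by a digitized Euclidean ball via mask shifting
brute_dilate <- function(mask, r) {
  d <- dim(mask)
  out <- array(FALSE, d)
  for (dz in -r:r) for (dx in -r:r) for (dy in -r:r) {
    if (dy^2 + dx^2 + dz^2 > r^2) next
    sy <- intersect(seq_len(d[1]), seq_len(d[1]) - dy)
    sx <- intersect(seq_len(d[2]), seq_len(d[2]) - dx)
    sz <- intersect(seq_len(d[3]), seq_len(d[3]) - dz)
    out[sy + dy, sx + dx, sz + dz] <-
      out[sy + dy, sx + dx, sz + dz] | mask[sy, sx, sz]
  }
  out
}

# closing oracle with the same border convention as close_matrix()
brute_close <- function(mask, r) {
  d <- dim(mask)
  pad <- array(FALSE, d + 2L * r)
  pad[r + seq_len(d[1]), r + seq_len(d[2]), r + seq_len(d[3])] <- mask
  dil <- brute_dilate(pad, r)
  ero <- !brute_dilate(!dil, r)
  ero[r + seq_len(d[1]), r + seq_len(d[2]), r + seq_len(d[3]), drop = FALSE]
}

# 6-connected component count over a logical array (BFS; small masks only)
n_components <- function(mask) {
  d <- dim(mask)
  idx <- which(mask)
  if (!length(idx)) return(0L)
  pos <- arrayInd(idx, d)
  lin <- setNames(seq_along(idx), idx)
  visited <- logical(length(idx))
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  ncomp <- 0L
  for (s in seq_along(idx)) {
    if (visited[s]) next
    ncomp <- ncomp + 1L
    queue <- s
    visited[s] <- TRUE
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      p <- pos[cur, ]
      for (o in seq_len(6)) {
        q <- p + offs[o, ]
        if (any(q < 1L) || any(q > d)) next
        l <- as.character(q[1] + d[1] * (q[2] - 1L) +
                            d[1] * d[2] * (q[3] - 1L))
        j <- lin[l]
        if (!is.na(j) && !visited[j]) {
          visited[j] <- TRUE
          queue <- c(queue, j)
        }
      }
    }
  }
  ncomp
}

# area-weighted mean curvature of a curvature field
weighted_mean_curvature <- function(field) {
  sum(field$curvature_mm * field$weight_um2) / sum(field$weight_um2)
}

# thickness at which a cumulative distribution first reaches 50%
median_thickness <- function(dist) {
  dist$thickness_um[which(dist$cum_pct >= 50)[1]]
}
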