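# shared fixtures and independent brute-force oracles

# centered uniform disc phantom
disc_phantom <- function(width, radius, value = 1) {
  ax <- seq_len(width) - (width + 1) / 2
  (outer(ax^2, ax^2, `+`) <= radius^2) * value
}

# nested-loop ray-sum Radon oracle: for each angle/detector position, walk
# the ray in 1-px steps and accumulate bilinear samples -- independent of
# the compiled projector
radon_oracle <- function(img, angles_deg, offset_px = 0,
                         detector_width = ncol(img)) {
  h <- nrow(img); w <- ncol(img)
  bilin <- function(x, y) {
    cj <- x + 0.5 * (w - 1) + 1; ci <- y + 0.5 * (h - 1) + 1
    j0 <- floor(cj); i0 <- floor(ci)
    fj <- cj - j0; fi <- ci - i0
    val <- 0
    for (di in 0:1) for (dj in 0:1) {
      i <- i0 + di; j <- j0 + dj
      if (i >= 1 && i <= h && j >= 1 && j <= w)
        val <- val + (if (di) fi else 1 - fi) * (if (dj) fj else 1 - fj) *
          img[i, j]
    }
    val
  }
  nt <- ceiling(sqrt(h^2 + w^2) + 2)
  ts <- -nt / 2 + seq_len(nt) - 0.5
  s <- offset_px - detector_width / 2 + seq_len(detector_width) - 0.5
  out <- matrix(0, length(angles_deg), detector_width)
  for (a in seq_along(angles_deg)) {
    th <- angles_deg[a] * pi / 180
    for (k in seq_along(s)) {
      acc <- 0
      for (t in ts)
        acc <- acc + bilin(s[k] * cos(th) - t * sin(th),
                           s[k] * sin(th) + t * cos(th))
      out[a, k] <- acc
    }
  }
  out
}

# iterative-dilation flood fill oracle (26-connectivity)
flood_oracle <- function(candidate, seed) {
  dims <- dim(candidate)
  vis <- array(FALSE, dims)
  vis[seed[1], seed[2], seed[3]] <- TRUE
  repeat {
    prev <- vis
    idx <- which(prev, arr.ind = TRUE)
    for (r in seq_len(nrow(idx))) {
      xs <- max(1, idx[r, 1] - 1):min(dims[1], idx[r, 1] + 1)
      ys <- max(1, idx[r, 2] - 1):min(dims[2], idx[r, 2] + 1)
      zs <- max(1, idx[r, 3] - 1):min(dims[3], idx[r, 3] + 1)
      vis[xs, ys, zs] <- vis[xs, ys, zs] | candidate[xs, ys, zs]
    }
    if (identical(vis, prev)) return(vis)
  }
}

# O(n^2) nearest-background search
edt_oracle <- function(mask) {
  bg <- which(!mask, arr.ind = TRUE)
  fg <- which(mask, arr.ind = TRUE)
  out <- array(0, dim(mask))
  for (r in seq_len(nrow(fg)))
    out[fg[r, 1], fg[r, 2], fg[r, 3]] <-
      min(sqrt(rowSums((t(t(bg) - fg[r, ]))^2)))
  out
}

# exhaustive between-class-variance scan over all histogram bins
otsu_oracle <- function(v, n_bins = 256) {
  rng <- range(v)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- tabulate(pmin(findInterval(v, edges, rightmost.closed = TRUE),
                     n_bins), n_bins)
  centers <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  best <- -Inf; bk <- 1
  for (k in seq_len(n_bins)) {
    w0 <- sum(h[1:k]); w1 <- sum(h) - w0
    if (w0 == 0 || w1 == 0) next
    m0 <- sum(h[1:k] * centers[1:k]) / w0
    m1 <- sum(h[(k + 1):n_bins] * centers[(k + 1):n_bins]) / w1
    sb <- w0 * w1 * (m0 - m1)^2
    if (sb > best) { best <- sb; bk <- k }
  }
  edges[bk + 1]
}
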