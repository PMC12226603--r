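# Independent oracles used across tests. These are deliberately naive
# (dense, fine-step, direct-summation) implementations, kept separate from the
# package's own code paths.

# Fine-step ray marching: per-pixel traversal lengths of the segment
# (x0,z0)-(x1,z1) through a grid, by sampling midpoints at step h.
march_lengths <- function(x0, z0, x1, z1, grid, h = NULL) {
  n_ax <- grid$n_ax; n_lat <- grid$n_lat
  out <- numeric(n_ax * n_lat)
  len <- sqrt((x1 - x0)^2 + (z1 - z0)^2)
  if (len == 0) return(out)
  if (is.null(h)) h <- min(grid$pitch_ax, grid$pitch_lat) / 5000
  n <- ceiling(len / h)
  hh <- len / n
  tm <- (seq_len(n) - 0.5) / n
  xs <- x0 + tm * (x1 - x0)
  zs <- z0 + tm * (z1 - z0)
  i_lat <- floor(xs / grid$pitch_lat)
  i_ax <- floor((zs - grid$depth_offset) / grid$pitch_ax)
  ok <- i_lat >= 0 & i_lat < n_lat & i_ax >= 0 & i_ax < n_ax
  if (!any(ok)) return(out)
  idx <- i_ax[ok] + n_ax * i_lat[ok] + 1
  tab <- rowsum(rep(hh, sum(ok)), idx)
  out[as.integer(rownames(tab))] <- tab[, 1]
  out
}

# Dense forward-model oracle: full round-trip (transmit leg + receive leg)
# per transmit, differenced per pair. Plane-wavefront transmit geometry.
dense_forward_oracle <- function(spec, grid, h = NULL) {
  lat <- (seq_len(grid$n_lat) - 0.5) * grid$pitch_lat
  ax <- grid$depth_offset + (seq_len(grid$n_ax) - 0.5) * grid$pitch_ax
  xc <- rep(lat, each = grid$n_ax)
  zc <- rep(ax, times = grid$n_lat)
  z_top <- grid$depth_offset
  npix <- grid$n_ax * grid$n_lat
  roundtrip <- lapply(spec$angles_deg, function(a) {
    th <- a * pi / 180
    M <- matrix(0, npix, npix)
    for (p in seq_len(npix)) {
      tx <- march_lengths(xc[p] - (zc[p] - z_top) * tan(th), z_top, xc[p], zc[p], grid, h)
      rx <- march_lengths(xc[p], z_top, xc[p], zc[p], grid, h)
      M[p, ] <- tx + rx
    }
    M
  })
  n_pairs <- spec$n_transmits - spec$pair_offset
  do.call(rbind, lapply(seq_len(n_pairs), function(p) {
    roundtrip[[p]] - roundtrip[[p + spec$pair_offset]]
  }))
}

# direct two-point linear interpolation with boundary clamping
interp_oracle <- function(knots, y, v) {
  sapply(v, function(vi) {
    if (vi <= knots[1]) return(y[1])
    nk <- length(knots)
    if (vi >= knots[nk]) return(y[nk])
    i <- max(which(knots <= vi))
    if (knots[i] == vi) return(y[i])
    a <- (vi - knots[i]) / (knots[i + 1] - knots[i])
    (1 - a) * y[i] + a * y[i + 1]
  })
}

# naive dense "same"-size cross-correlation with zero padding (R loops)
naive_corr2 <- function(x, k, a1, a2) {
  n <- nrow(x); m <- ncol(x); p <- nrow(k); q <- ncol(k)
  y <- matrix(0, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    acc <- 0
    for (u in seq_len(p)) for (v in seq_len(q)) {
      ii <- i + (u - 1) - a1; jj <- j + (v - 1) - a2
      if (ii >= 1 && ii <= n && jj >= 1 && jj <= m) acc <- acc + x[ii, jj] * k[u, v]
    }
    y[i, j] <- acc
  }
  y
}

# central finite-difference gradient of scalar function f at x (vector)
fd_grad <- function(f, x, h = 1e-6) {
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    g[i] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}

# exhaustive concordant-pair AUC oracle (ties get half credit)
auc_pair_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# exhaustive permutation-enumeration two-sided rank-sum p-value (midranks)
ranksum_perm_oracle <- function(a, b) {
  x <- c(a, b); n1 <- length(a); n <- length(x)
  rk <- rank(x)
  u_of <- function(idx) sum(rk[idx]) - n1 * (n1 + 1) / 2
  obs <- u_of(seq_len(n1))
  all_u <- apply(utils::combn(n, n1), 2, u_of)
  mid <- n1 * (n - n1) / 2
  p <- 2 * min(mean(all_u <= obs), mean(all_u >= obs))
  min(1, p)
}

rand_slowness_dev <- function(grid, sd = 1e-8, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(rnorm(grid$n_ax * grid$n_lat, sd = sd), grid$n_ax, grid$n_lat)
}
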