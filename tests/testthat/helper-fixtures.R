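# Shared fixture builders. Everything is generated in code; nothing is read
# from disk.

# Four Gaussian blobs at long lever arms: enough asymmetric structure to
# constrain all six rigid degrees of freedom.
registration_phantom <- function(centers = reg_centers(), scale = 1,
                                 spacing = 1.5, dims = 32) {
  sig <- c(5, 4, 4, 6) * scale
  pk <- c(100, 60, 80, 70)
  shapes <- lapply(1:4, function(i)
    list(type = "gaussian_blob", center = scale * centers[i, ],
         sigma = sig[i], peak = pk[i]))
  make_phantom(phantom_spec(rep(dims, 3), rep(spacing, 3), shapes = shapes,
                            modality = "MR"))
}

reg_centers <- function() rbind(c(-15, 8, 0), c(16, -10, 8),
                                c(0, 14, -14), c(-6, -12, 12))

# random test volume with a fixed seed
random_volume <- function(dims, spacing = c(1, 1, 1), seed = 1,
                          value_kind = "unitless", lo = 0, hi = 10) {
  set.seed(seed)
  image_volume(array(runif(prod(dims), lo, hi), dims),
               grid_geometry(dims, spacing), value_kind = value_kind)
}

# brute-force statistics oracle: plain voxel loop
brute_force_statistics <- function(vol, voi) {
  vals <- c()
  d <- dim(vol$voxels)
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1]))
    if (voi$mask[i, j, k]) vals <- c(vals, vol$voxels[i, j, k])
  list(n = length(vals), total = sum(vals), mean = mean(vals),
       min = min(vals), max = max(vals),
       sd = sqrt(mean((vals - mean(vals))^2)))
}

# brute-force 3-D convolution oracle (direct loop over kernel taps)
brute_force_convolve <- function(x, k) {
  dx <- dim(x); dk <- dim(k); c0 <- (dk + 1) %/% 2
  out <- array(0, dx)
  for (ik in 1:dk[1]) for (jk in 1:dk[2]) for (kk in 1:dk[3]) {
    w <- k[ik, jk, kk]
    if (w == 0) next
    for (i in 1:dx[1]) for (j in 1:dx[2]) for (l in 1:dx[3]) {
      si <- i - (ik - c0[1]); sj <- j - (jk - c0[2]); sl <- l - (kk - c0[3])
      if (si >= 1 && si <= dx[1] && sj >= 1 && sj <= dx[2] &&
          sl >= 1 && sl <= dx[3])
        out[i, j, l] <- out[i, j, l] + w * x[si, sj, sl]
    }
  }
  out
}

# brute-force flood fill component count (6 or 26 connectivity)
brute_force_components <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  lab <- array(0L, d)
  nb <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nb <- nb[rowSums(abs(nb)) > 0, ]
  if (connectivity == 6L) nb <- nb[rowSums(abs(nb)) == 1, ]
  cur <- 0L
  for (s in which(mask)) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    lab[s] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      p <- arrayInd(v, d)
      for (r in seq_len(nrow(nb))) {
        q <- p + nb[r, ]
        if (any(q < 1) || any(q > d)) next
        ql <- q[1] + d[1] * (q[2] - 1) + d[1] * d[2] * (q[3] - 1)
        if (mask[ql] && lab[ql] == 0L) { lab[ql] <- cur; queue <- c(queue, ql) }
      }
    }
  }
  cur
}
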