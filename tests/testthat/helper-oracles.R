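# Independent reference implementations used to cross-check the package.
# All are deliberately naive (triple loops, explicit formulas) and share no
# code with the implementation paths they validate.

# Jacobian determinant of x -> x + u(x) built voxel-by-voxel from the full
# 3x3 finite-difference matrix (central interior, one-sided at boundaries).
oracle_jacobian_det <- function(u, voxel_size_mm) {
  d <- dim(u)[1:3]
  out <- array(NA_real_, d)
  dcomp <- function(ci, x, y, z, axis) {
    idx <- c(x, y, z)
    n <- d[axis]
    lo <- idx; hi <- idx
    if (idx[axis] == 1) { hi[axis] <- 2; h <- voxel_size_mm[axis] }
    else if (idx[axis] == n) { lo[axis] <- n - 1; h <- voxel_size_mm[axis] }
    else { lo[axis] <- idx[axis] - 1; hi[axis] <- idx[axis] + 1
           h <- 2 * voxel_size_mm[axis] }
    (u[hi[1], hi[2], hi[3], ci] - u[lo[1], lo[2], lo[3], ci]) / h
  }
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    J <- matrix(0, 3, 3)
    for (ci in 1:3) for (ax in 1:3) J[ci, ax] <- dcomp(ci, x, y, z, ax)
    out[x, y, z] <- det(diag(3) + J)
  }
  out
}

# Connected components by breadth-first search over an explicit neighbour
# offset table. Returns an integer label array (labels in BFS-discovery
# order, which may differ from the implementation's ordering).
oracle_bfs_label <- function(mask, connectivity) {
  d <- dim(mask)
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  m <- abs(offs$dx) + abs(offs$dy) + abs(offs$dz)
  keep <- m > 0 & m <= switch(as.character(connectivity),
                              "6" = 1, "18" = 2, "26" = 3)
  offs <- offs[keep, ]
  labels <- array(0L, d)
  lab <- 0L
  coords <- which(mask, arr.ind = TRUE)
  for (k in seq_len(nrow(coords))) {
    v <- coords[k, ]
    if (labels[v[1], v[2], v[3]] != 0L) next
    lab <- lab + 1L
    queue <- list(v)
    labels[v[1], v[2], v[3]] <- lab
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (j in seq_len(nrow(offs))) {
        q <- p + c(offs$dx[j], offs$dy[j], offs$dz[j])
        if (any(q < 1) || any(q > d)) next
        if (mask[q[1], q[2], q[3]] && labels[q[1], q[2], q[3]] == 0L) {
          labels[q[1], q[2], q[3]] <- lab
          queue <- c(queue, list(q))
        }
      }
    }
  }
  labels
}

# TRUE when two label maps define the same partition of foreground voxels.
same_partition <- function(a, b) {
  if (!identical(a > 0, b > 0)) return(FALSE)
  fg <- which(a > 0)
  if (!length(fg)) return(TRUE)
  key <- paste(a[fg], b[fg])
  length(unique(key)) == length(unique(a[fg])) &&
    length(unique(key)) == length(unique(b[fg]))
}

# Efron-tie partial log-likelihood for a single covariate.
oracle_efron_loglik <- function(beta, time, event, x) {
  eta <- beta * x
  w <- exp(eta)
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    D <- which(time == t & event == 1)
    R <- which(time >= t)
    d <- length(D)
    sumD <- sum(w[D])
    sumR <- sum(w[R])
    ll <- ll + sum(eta[D])
    for (l in seq_len(d) - 1)
      ll <- ll - log(sumR - (l / d) * sumD)
  }
  ll
}

oracle_efron_mle <- function(time, event, x, lower = -8, upper = 8) {
  opt <- optimize(function(b) oracle_efron_loglik(b, time, event, x),
                  c(lower, upper), maximum = TRUE, tol = 1e-10)
  list(beta = opt$maximum, loglik = opt$objective,
       lr = 2 * (opt$objective - oracle_efron_loglik(0, time, event, x)))
}

# Small helper: stack of normalized maps from a 4-D array.
as_norm_maps <- function(arr4d, voxel_size_mm = c(1, 1, 1)) {
  lapply(seq_len(dim(arr4d)[4]), function(i)
    log_jacobian_map(array(arr4d[, , , i], dim(arr4d)[1:3]),
                     "normalized-2yr", voxel_size_mm))
}
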