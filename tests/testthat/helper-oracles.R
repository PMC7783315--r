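# Independent oracles used to validate the superposition code paths.
# These deliberately avoid the package's own Kabsch/TM implementations:
# the rotation-grid oracle searches rotation space directly, and the
# exhaustive TM oracle enumerates every contiguous seed window, using
# bio3d's least-squares fit for its superpositions.

euler_rotation <- function(a, b, c) {
  rz <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3, 3)
  ry <- function(t) matrix(c(cos(t), 0, -sin(t), 0, 1, 0, sin(t), 0, cos(t)), 3, 3)
  rz(a) %*% ry(b) %*% rz(c)
}

# Brute-force minimum RMSD over rigid transforms: optimal translation is
# centroid matching (closed form); the rotation is searched on a coarse
# Euler-angle grid and refined locally with Nelder-Mead. Depends on the
# rotation only through tr(R %*% A), A = sum_i a_i b_i^T.
oracle_min_rmsd <- function(X, Y, grid_step = 15) {
  n <- nrow(X)
  Xc <- sweep(X, 2, colMeans(X)); Yc <- sweep(Y, 2, colMeans(Y))
  A <- t(Xc) %*% Yc
  const <- sum(Xc^2) + sum(Yc^2)
  obj <- function(ang) -sum(euler_rotation(ang[1], ang[2], ang[3]) * t(A))
  step <- grid_step * pi / 180
  grid <- expand.grid(a = seq(0, 2 * pi - step, by = step),
                      b = seq(0, pi, by = step),
                      c = seq(0, 2 * pi - step, by = step))
  vals <- apply(as.matrix(grid), 1, obj)
  starts <- as.matrix(grid)[order(vals)[1:5], , drop = FALSE]
  best <- Inf
  for (k in seq_len(nrow(starts))) {
    fit <- stats::optim(starts[k, ], obj, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-14))
    best <- min(best, fit$value)
  }
  sqrt(max(0, (const + 2 * best)) / n)
}

# superpose X[set,] onto Y[set,] by bio3d least squares; return all-pair distances
oracle_fit_dists <- function(X, Y, set) {
  Xf <- bio3d::rot.lsq(xx = as.numeric(t(X)), yy = as.numeric(t(Y)),
                       xfit = rep(seq_len(nrow(X)) %in% set, each = 3))
  Xf <- matrix(Xf, ncol = 3, byrow = TRUE)
  sqrt(rowSums((Xf - Y)^2))
}

# Exhaustive-seed TM maximum: every offset of every seed window length in
# the defining schedule (L, L/2, L/4, floor of 4), each refined by the
# include/re-superpose iteration over the d_cut schedule. Written against
# bio3d's fitting engine so it shares no code with the package's search.
oracle_tm_max <- function(X, Y, l_norm) {
  n <- nrow(X)
  d0 <- if (l_norm <= 21) 0.5 else max(0.5, 1.24 * (l_norm - 15)^(1 / 3) - 1.8)
  d_cuts <- unique(c(seq(min(d0 + 1, 8), 8, by = 0.5), 8))
  best <- -Inf
  wls <- sort(unique(pmax(4, c(n, n %/% 2, n %/% 4))))
  for (wl in wls) for (off in 1:(n - wl + 1)) {
    set <- off:(off + wl - 1)
    for (d_cut in d_cuts) {
      for (it in 1:30) {
        if (length(set) < 3) break
        dists <- oracle_fit_dists(X, Y, set)
        tm <- sum(1 / (1 + (dists / d0)^2)) / l_norm
        best <- max(best, tm)
        new_set <- which(dists < d_cut)
        if (length(new_set) < 3 || identical(new_set, set)) break
        set <- new_set
      }
    }
  }
  best
}

# random non-degenerate point cloud
random_points <- function(n, spread = 10) {
  matrix(stats::runif(3 * n, -spread, spread), ncol = 3)
}

make_pair_models <- function(n, sigma, seed) {
  base <- make_helix_rod(n, model_id = "a")
  moved <- random_rigid_move(perturb_model(base, sigma, seed), seed + 1000L)$model
  moved$model_id <- "b"
  list(a = base, b = moved)
}
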