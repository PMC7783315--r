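#' Construct a rigid transform
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation 3-vector, Angstrom.
#' @return An object of class `RigidTransform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  stopifnot(all(dim(rotation) == c(3L, 3L)), length(translation) == 3L)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8)
    stop("rotation is not orthonormal")
  if (abs(det(rotation) - 1) > 1e-8)
    stop("rotation must be proper (det = +1)")
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "RigidTransform")
}

#' @export
print.RigidTransform <- function(x, ...) {
  cat("RigidTransform\n  rotation:\n")
  print(round(x$rotation, 6))
  cat("  translation:", paste(round(x$translation, 4), collapse = ", "), "\n")
  invisible(x)
}

apply_transform <- function(xyz, transform) {
  sweep(xyz %*% t(transform$rotation), 2L, transform$translation, "+")
}

as_paired_xyz <- function(x) {
  if (inherits(x, "ChainModel")) return(x$ca)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (ncol(x) != 3L) stop("coordinates must be n x 3")
  x
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares rigid superposition of paired coordinate sets by singular
#' value decomposition of the cross-covariance matrix, with the standard
#' reflection correction so the returned rotation is always proper
#' (det = +1). The transform maps `mobile` onto `target`:
#' `y_hat = R x + t`, minimising the RMSD over all rigid transforms for the
#' given pairing.
#'
#' @param mobile,target paired coordinates: n x 3 matrices (or `ChainModel`s
#'   of equal length whose residues correspond row-by-row). At least 3
#'   non-collinear pairs are required.
#' @param normalization_length length used for the TM-score style
#'   normalisation reported alongside the RMSD; defaults to the number of
#'   pairs.
#' @return A `SuperpositionResult`: list with `transform`
#'   ([rigid_transform()]), `rmsd` (Angstrom, over the given pairing),
#'   `tm_score` (computed for this single superposition, not search-maximised),
#'   `n_pairs`, and `normalization_length`.
#' @export
kabsch_superpose <- function(mobile, target, normalization_length = NULL) {
  X <- as_paired_xyz(mobile)
  Y <- as_paired_xyz(target)
  if (nrow(X) != nrow(Y)) stop("mobile and target must have the same number of pairs")
  n <- nrow(X)
  if (n < 3L) stop("at least 3 paired points are required")
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2L, cx); Yc <- sweep(Y, 2L, cy)
  sv_chk <- svd(Xc, nu = 0, nv = 0)$d
  if (sv_chk[2] < 1e-8 * max(sv_chk[1], 1))
    stop("points are collinear; rotation is underdetermined")
  H <- crossprod(Xc, Yc)                # 3x3 cross-covariance
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tvec <- cy - as.numeric(R %*% cx)
  tr <- rigid_transform(R, tvec)
  dif <- apply_transform(X, tr) - Y
  dists <- sqrt(rowSums(dif * dif))
  rmsd <- sqrt(mean(dists^2))
  L <- if (is.null(normalization_length)) n else as.integer(normalization_length)
  structure(list(transform = tr, rmsd = rmsd,
                 tm_score = sum(1 / (1 + (dists / tm_d0(L))^2)) / L,
                 n_pairs = n, normalization_length = L),
            class = "SuperpositionResult")
}

#' @export
print.SuperpositionResult <- function(x, ...) {
  cat(sprintf("SuperpositionResult: %d pairs, RMSD %.3f A, TM-score %.4f (L_norm = %d)\n",
              x$n_pairs, x$rmsd, x$tm_score, x$normalization_length))
  invisible(x)
}

#' TM-score distance scale d0
#'
#' `d0 = 1.24 (L - 15)^(1/3) - 1.8`, clamped below at 0.5 Angstrom: for
#' normalisation lengths of 21 or less the cube-root formula would drop
#' below 0.5 (or become undefined), so the conventional floor is applied.
#'
#' @param l_norm normalisation length.
#' @return d0 in Angstrom.
#' @export
tm_d0 <- function(l_norm) {
  if (l_norm <= 21) return(0.5)
  max(0.5, 1.24 * (l_norm - 15)^(1 / 3) - 1.8)
}

tm_value <- function(dists, d0, l_norm) sum(1 / (1 + (dists / d0)^2)) / l_norm

# one seed-and-extend pass: superpose on `set`, then alternately include
# pairs closer than d_cut and re-superpose until the included set is stable;
# d_cut walks the schedule upward. Returns the best TM seen and its transform.
tm_extend <- function(X, Y, set, d0, l_norm, d_cuts, max_iter = 30L) {
  best <- list(tm = -Inf, transform = NULL)
  for (d_cut in d_cuts) {
    for (it in seq_len(max_iter)) {
      if (length(set) < 3L) break
      fit <- tryCatch(kabsch_superpose(X[set, , drop = FALSE], Y[set, , drop = FALSE]),
                      error = function(e) NULL)
      if (is.null(fit)) break
      dif <- apply_transform(X, fit$transform) - Y
      dists <- sqrt(rowSums(dif * dif))
      tm <- tm_value(dists, d0, l_norm)
      if (tm > best$tm) best <- list(tm = tm, transform = fit$transform)
      new_set <- which(dists < d_cut)
      if (length(new_set) < 3L || identical(new_set, set)) break
      set <- new_set
    }
  }
  best
}

#' Length-normalised structural similarity (TM-score)
#'
#' TM-score between two models over a residue pairing:
#' `TM = max over superpositions of (1/L_norm) * sum_i 1 / (1 + (d_i/d0)^2)`
#' with `d0` from [tm_d0()]. The maximisation uses the standard
#' seed-and-extend search: contiguous seed windows of length L, L/2 and L/4
#' (minimum 4) at every offset are superposed by Kabsch, then pairs within a
#' distance cutoff are iteratively re-included and re-superposed for a
#' cutoff schedule running from `d0 + 1` up to 8 Angstrom; the maximum TM
#' over all seeds is reported. Identical structures score exactly
#' `n_pairs / L_norm` (i.e. 1 when the pairing covers the normalisation
#' length).
#'
#' @param mobile,target `ChainModel`s in the same scheme.
#' @param pairing optional two-column index matrix as returned by
#'   [shared_residue_pairing()]; computed from shared residue numbers when
#'   omitted.
#' @param normalization_length length L_norm used in the score; defaults to
#'   the number of residues of `target`.
#' @return A `SuperpositionResult` whose `tm_score` is the search maximum
#'   and whose `rmsd` is measured over the full pairing under the
#'   TM-optimal transform.
#' @export
tm_score <- function(mobile, target, pairing = NULL, normalization_length = NULL) {
  if (is.null(pairing)) pairing <- shared_residue_pairing(mobile, target)
  if (nrow(pairing) == 0L) stop("empty pairing: no shared residues")
  X <- mobile$ca[pairing[, 1], , drop = FALSE]
  Y <- target$ca[pairing[, 2], , drop = FALSE]
  n <- nrow(X)
  l_norm <- if (is.null(normalization_length)) length(target)
            else as.integer(normalization_length)
  d0 <- tm_d0(l_norm)
  d_cuts <- unique(c(seq(min(d0 + 1, 8), 8, by = 0.5), 8))
  win_lens <- sort(unique(pmax(4L, c(n, n %/% 2L, n %/% 4L))))
  win_lens <- win_lens[win_lens <= n]
  best <- list(tm = -Inf, transform = NULL)
  for (wl in win_lens) {
    for (off in seq_len(n - wl + 1L)) {
      cand <- tm_extend(X, Y, off:(off + wl - 1L), d0, l_norm, d_cuts)
      if (cand$tm > best$tm) best <- cand
    }
  }
  if (!is.finite(best$tm)) stop("TM search failed (degenerate coordinates)")
  dif <- apply_transform(X, best$transform) - Y
  structure(list(transform = best$transform,
                 rmsd = sqrt(mean(rowSums(dif * dif))),
                 tm_score = best$tm, n_pairs = n,
                 normalization_length = l_norm),
            class = "SuperpositionResult")
}

#' All-vs-all model comparison matrix
#'
#' For every model pair: residue pairing by shared residue numbers
#' (optionally restricted to a window such as the 186-698 proteinase core),
#' full-pairing Kabsch RMSD, and TM-score normalised by the length of the
#' column model (so the matrix may be asymmetric in TM; both normalisations
#' are therefore present, one per triangle). Pairs sharing fewer than 3
#' residues yield missing cells rather than an error.
#'
#' @param models list of `ChainModel`s (>= 2), same scheme.
#' @param window optional `c(first, last)` residue-number window.
#' @return A `ComparisonMatrix`: list with `model_ids`, `rmsd`, `tm`
#'   (`tm[i, j]` = TM of model i against model j, normalised by model j's
#'   length within the window), and `shared` counts.
#' @export
compare_all <- function(models, window = NULL) {
  if (length(models) < 2L) stop("need at least 2 models")
  ids <- vapply(models, function(m) m$model_id, character(1))
  if (anyDuplicated(ids)) ids <- make.unique(ids)
  k <- length(models)
  rmsd <- tm <- matrix(NA_real_, k, k, dimnames = list(ids, ids))
  shared <- matrix(0L, k, k, dimnames = list(ids, ids))
  if (!is.null(window)) {
    models <- lapply(models, function(m) {
      keep <- m$seq_index[m$seq_index >= window[1] & m$seq_index <= window[2]]
      if (length(keep) == 0L) m else chain_subset(m, keep)
    })
  }
  diag(rmsd) <- 0; diag(tm) <- 1
  for (i in seq_len(k)) shared[i, i] <- length(models[[i]])
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    pr <- shared_residue_pairing(models[[i]], models[[j]])
    shared[i, j] <- shared[j, i] <- nrow(pr)
    if (nrow(pr) < 3L) next
    fit <- tryCatch(kabsch_superpose(models[[i]]$ca[pr[, 1], ],
                                     models[[j]]$ca[pr[, 2], ]),
                    error = function(e) NULL)
    if (is.null(fit)) next
    rmsd[i, j] <- rmsd[j, i] <- fit$rmsd
    tm[i, j] <- tm_score(models[[i]], models[[j]], pr,
                         normalization_length = length(models[[j]]))$tm_score
    tm[j, i] <- tm_score(models[[j]], models[[i]], pr[, 2:1, drop = FALSE],
                         normalization_length = length(models[[i]]))$tm_score
  }
  structure(list(model_ids = ids, rmsd = rmsd, tm = tm, shared = shared),
            class = "ComparisonMatrix")
}

#' @export
print.ComparisonMatrix <- function(x, ...) {
  cat("ComparisonMatrix over", length(x$model_ids), "models\nTM-score:\n")
  print(round(x$tm, 3))
  cat("RMSD (A):\n")
  print(round(x$rmsd, 3))
  invisible(x)
}

#' Select the ensemble reference (medoid) model
#'
#' Picks the model "differing the least from any of the others", the natural
#' superposition target for an ensemble. TM values are symmetrised (mean of
#' the two normalisations) before aggregation; missing cells are ignored.
#' Ties break lexicographically by model id, so selection is deterministic.
#'
#' @param matrix a `ComparisonMatrix`.
#' @param criterion `"max_min_tm"` (default; maximise the worst-case TM to
#'   any other model), `"max_mean_tm"`, or `"min_mean_rmsd"`.
#' @return The selected model id (character).
#' @export
select_reference <- function(matrix,
                             criterion = c("max_min_tm", "max_mean_tm", "min_mean_rmsd")) {
  criterion <- match.arg(criterion)
  ids <- matrix$model_ids
  if (length(ids) == 0L) stop("empty comparison matrix")
  tm_sym <- (matrix$tm + t(matrix$tm)) / 2
  score <- vapply(seq_along(ids), function(i) {
    if (criterion == "min_mean_rmsd") {
      v <- matrix$rmsd[i, -i]
      if (all(is.na(v))) return(Inf)
      -mean(v, na.rm = TRUE)          # negate: higher is always better below
    } else {
      v <- tm_sym[i, -i]
      if (all(is.na(v))) return(-Inf)
      if (criterion == "max_min_tm") min(v, na.rm = TRUE)
      else mean(v, na.rm = TRUE)
    }
  }, numeric(1))
  best <- which(score == max(score))
  ids[best][order(ids[best])][1]
}

#' Export a comparison matrix as TSV
#'
#' Writes the requested component with model ids as header row and column.
#'
#' @param matrix a `ComparisonMatrix`.
#' @param path output path.
#' @param what `"tm"`, `"rmsd"`, or `"shared"`.
#' @return Invisibly, `path`.
#' @export
write_comparison_matrix <- function(matrix, path, what = c("tm", "rmsd", "shared")) {
  what <- match.arg(what)
  m <- matrix[[what]]
  df <- data.frame(model_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
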