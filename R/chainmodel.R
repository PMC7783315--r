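#' Construct a ChainModel
#'
#' A `ChainModel` is the residue-indexed C-alpha trace used throughout the
#' package: one protein chain, each residue carrying its residue number in a
#' declared coordinate scheme (see [coordinate_schemes()]), a one-letter
#' amino-acid code, and a 3-vector of C-alpha coordinates in Angstrom.
#' Optional non-CA atoms (e.g. side-chain atoms of catalytic residues) are
#' carried in `extra_atoms`.
#'
#' @param model_id character label for the model (e.g. `"iTAS_2"`).
#' @param scheme coordinate-scheme tag; one of the names returned by
#'   [coordinate_schemes()].
#' @param seq_index integer vector of residue numbers, strictly increasing,
#'   all >= 1.
#' @param aa character vector of one-letter amino-acid codes (`"X"` for
#'   unknown), same length as `seq_index`.
#' @param ca numeric matrix with one row per residue and columns x, y, z
#'   (Angstrom). All components must be finite.
#' @param extra_atoms optional data.frame with columns `seq_index`, `atom`,
#'   `x`, `y`, `z` for additional named atoms.
#' @return An object of class `ChainModel`.
#' @export
chain_model <- function(model_id, scheme, seq_index, aa, ca, extra_atoms = NULL) {
  seq_index <- as.integer(seq_index)
  if (length(seq_index) == 0L)
    stop("ChainModel must contain at least one residue")
  if (anyNA(seq_index) || any(seq_index < 1L))
    stop("seq_index must be >= 1 and non-missing")
  if (is.unsorted(seq_index, strictly = TRUE))
    stop("seq_index must be strictly increasing (duplicate or out-of-order residue numbers)")
  ca <- as.matrix(ca)
  if (is.null(dim(ca)) || ncol(ca) != 3L)
    stop("ca must be an n x 3 coordinate matrix")
  storage.mode(ca) <- "double"
  if (nrow(ca) != length(seq_index))
    stop("ca must have one row per residue")
  if (!all(is.finite(ca)))
    stop("ca coordinates must be finite")
  aa <- as.character(aa)
  if (length(aa) != length(seq_index))
    stop("aa must have one entry per residue")
  dimnames(ca) <- list(NULL, c("x", "y", "z"))
  if (!is.null(extra_atoms)) {
    stopifnot(is.data.frame(extra_atoms),
              all(c("seq_index", "atom", "x", "y", "z") %in% names(extra_atoms)))
    if (!all(extra_atoms$seq_index %in% seq_index))
      stop("extra_atoms reference residue numbers absent from the chain")
  }
  structure(
    list(model_id = as.character(model_id)[1], scheme = as.character(scheme)[1],
         seq_index = seq_index, aa = aa, ca = ca, extra_atoms = extra_atoms),
    class = "ChainModel")
}

#' @export
print.ChainModel <- function(x, ...) {
  rng <- range(x$seq_index)
  cat(sprintf("ChainModel '%s' [%s]: %d residues, numbered %d..%d\n",
              x$model_id, x$scheme, length(x$seq_index), rng[1], rng[2]))
  invisible(x)
}

#' @export
length.ChainModel <- function(x) length(x$seq_index)

#' Restrict a ChainModel to a set of residue numbers
#'
#' @param model a `ChainModel`.
#' @param seq_indices residue numbers to keep (order is ignored; the result
#'   keeps chain order).
#' @return A `ChainModel` containing only the requested residues.
#' @export
chain_subset <- function(model, seq_indices) {
  keep <- model$seq_index %in% seq_indices
  if (!any(keep)) stop("no residues left after subsetting")
  extra <- model$extra_atoms
  if (!is.null(extra)) {
    extra <- extra[extra$seq_index %in% model$seq_index[keep], , drop = FALSE]
    if (nrow(extra) == 0L) extra <- NULL
  }
  chain_model(model$model_id, model$scheme,
              model$seq_index[keep], model$aa[keep],
              model$ca[keep, , drop = FALSE], extra)
}

#' Apply a rigid transform to a ChainModel
#'
#' @param model a `ChainModel`.
#' @param transform a `RigidTransform` as produced by [rigid_transform()] or
#'   returned inside a superposition result.
#' @return The transformed `ChainModel` (y = R x + t applied to every atom).
#' @export
chain_transform <- function(model, transform) {
  R <- transform$rotation; tvec <- transform$translation
  ca <- model$ca %*% t(R)
  ca <- sweep(ca, 2L, tvec, "+")
  extra <- model$extra_atoms
  if (!is.null(extra)) {
    xyz <- as.matrix(extra[, c("x", "y", "z")]) %*% t(R)
    xyz <- sweep(xyz, 2L, tvec, "+")
    extra[, c("x", "y", "z")] <- xyz
  }
  chain_model(model$model_id, model$scheme, model$seq_index, model$aa, ca, extra)
}

# run code with a private RNG state so generators are pure in (params, seed)
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}
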