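#' Construct a per-segment contact map
#'
#' Sparse predicted residue-residue contact probabilities for one sequence
#' segment, in LOCAL coordinates (position 1 = `offset` in the full
#' sequence). Entries are stored upper-triangular (`i < j`).
#'
#' @param offset global residue index of local position 1.
#' @param length segment length in residues.
#' @param entries data.frame with columns `i`, `j`, `p` (local indices,
#'   probability in `[0, 1]`).
#' @return An object of class `SegmentContactMap`.
#' @export
segment_contact_map <- function(offset, length, entries) {
  offset <- as.integer(offset); length <- as.integer(length)
  stopifnot(offset >= 1L, length >= 2L)
  entries <- as.data.frame(entries)[, c("i", "j", "p")]
  entries$i <- as.integer(entries$i); entries$j <- as.integer(entries$j)
  swap <- entries$i > entries$j
  if (any(swap)) entries[swap, c("i", "j")] <- entries[swap, c("j", "i")]
  if (any(entries$i == entries$j)) stop("self-contacts (i == j) are invalid")
  if (any(entries$i < 1L | entries$j > length))
    stop("contact indices outside segment 1..", length)
  if (any(entries$p < 0 | entries$p > 1)) stop("probabilities must be in [0, 1]")
  structure(list(offset = offset, length = length,
                 entries = entries[order(entries$i, entries$j), , drop = FALSE]),
            class = "SegmentContactMap")
}

#' Load a contact map from 3-column text
#'
#' The interchange format is whitespace-separated `i j p` lines with `#`
#' comments, the form contact-prediction servers emit. Lines with `j < i`
#' are normalised to the upper triangle; duplicate pairs keep the maximum
#' probability with a warning.
#'
#' @param path input file.
#' @param offset global residue index of local position 1 (segments are
#'   delivered in local numbering with a known global offset).
#' @param length optional segment length; defaults to the largest index seen.
#' @return A `SegmentContactMap`.
#' @export
load_contact_map <- function(path, offset = 1L, length = NULL) {
  raw <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", raw)
  lineno <- which(keep)
  fields <- strsplit(trimws(raw[keep]), "\\s+")
  bad <- which(lengths(fields) < 3L)
  if (length(bad) > 0L)
    stop("line ", lineno[bad[1]], ": expected 3 columns (i j p)")
  i <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 1L)))
  j <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  p <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(i) | is.na(j) | is.na(p))
  if (length(bad) > 0L) stop("line ", lineno[bad[1]], ": non-numeric field")
  bad <- which(i == j)
  if (length(bad) > 0L) stop("line ", lineno[bad[1]], ": self-contact (i == j)")
  bad <- which(p < 0 | p > 1)
  if (length(bad) > 0L)
    stop("line ", lineno[bad[1]], ": probability ", p[bad[1]], " outside [0, 1]")
  lo <- pmin(i, j); hi <- pmax(i, j)
  dt <- data.table::data.table(i = lo, j = hi, p = p)
  if (anyDuplicated(dt, by = c("i", "j"))) {
    warning("duplicate contact pairs in ", path, "; keeping maximum probability")
    dt <- dt[, list(p = max(p)), by = c("i", "j")]
  }
  if (is.null(length)) length <- max(dt$j)
  segment_contact_map(offset, length, as.data.frame(dt))
}

#' Write a contact map or composite as 3-column text
#'
#' Composites gain a fourth `coverage` column.
#'
#' @param map a `SegmentContactMap` or `CompositeContactMap`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_contact_map <- function(map, path) {
  df <- if (inherits(map, "CompositeContactMap")) map$entries else map$entries
  utils::write.table(df, path, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Stitch overlapping segment maps into a full-length composite
#'
#' Contact prediction servers cap input length (the PrtP maps were computed
#' on overlapping ~800-residue windows), so per-segment maps must be
#' composited: each local entry is placed at
#' `i_global = i_local + offset - 1`, and predictions for the same global
#' pair from different segments are merged by `merge_rule`. The number of
#' contributing segments is recorded per pair as `coverage`.
#'
#' @param maps list of `SegmentContactMap`s.
#' @param L full sequence length; every segment must fit within `1..L`.
#' @param merge_rule `"mean"` (default), `"max"`, or `"min"`.
#' @return A `CompositeContactMap`: list with `L` and `entries`
#'   (`i`, `j`, `p`, `coverage`) in the global frame.
#' @export
stitch <- function(maps, L, merge_rule = c("mean", "max", "min")) {
  merge_rule <- match.arg(merge_rule)
  L <- as.integer(L)
  if (inherits(maps, "SegmentContactMap")) maps <- list(maps)
  for (m in maps) {
    if (m$offset + m$length - 1L > L)
      stop("segment ", m$offset, "..", m$offset + m$length - 1L,
           " exceeds full length L = ", L)
  }
  pieces <- lapply(maps, function(m) {
    data.table::data.table(i = m$entries$i + m$offset - 1L,
                           j = m$entries$j + m$offset - 1L,
                           p = m$entries$p)
  })
  dt <- data.table::rbindlist(pieces)
  if (nrow(dt) == 0L) {
    entries <- data.frame(i = integer(0), j = integer(0),
                          p = numeric(0), coverage = integer(0))
  } else {
    f <- switch(merge_rule, mean = mean, max = max, min = min)
    dt <- dt[, list(p = f(p), coverage = .N), by = c("i", "j")]
    data.table::setorder(dt, i, j)
    entries <- as.data.frame(dt)
  }
  structure(list(L = L, entries = entries), class = "CompositeContactMap")
}

#' @export
print.CompositeContactMap <- function(x, ...) {
  cat(sprintf("CompositeContactMap: L = %d, %d contact pairs, max coverage %s\n",
              x$L, nrow(x$entries),
              if (nrow(x$entries)) max(x$entries$coverage) else "NA"))
  invisible(x)
}

#' Render the 45-degree-tilted diagonal band of a composite map
#'
#' Because segment-based maps only cover pairs separated by less than a few
#' hundred residues, the natural display is the diagonal band "tilted by
#' 45 degrees": row = sequence position i, column = separation `j - i`.
#'
#' @param map a `CompositeContactMap`.
#' @param band maximum separation retained (default 200 residues); entries
#'   separated further are clipped.
#' @return A dense `L x band` numeric matrix; `[i, s]` holds the probability
#'   of the contact `(i, i + s)`, 0 where absent.
#' @export
render_diagonal_band <- function(map, band = 200L) {
  band <- as.integer(band)
  stopifnot(band >= 1L)
  m <- matrix(0, nrow = map$L, ncol = band)
  e <- map$entries
  if (nrow(e) > 0L) {
    sep <- e$j - e$i
    keep <- sep <= band
    m[cbind(e$i[keep], sep[keep])] <- e$p[keep]
  }
  dimnames(m) <- list(NULL, paste0("sep", seq_len(band)))
  m
}

# contact entries filtered to the probability floor and a separation cap
# (90th percentile of observed separations): boundary scoring must look at
# the densely populated near-diagonal band, not at sparse long-range noise.
boundary_entries <- function(map, p_min) {
  e <- map$entries[map$entries$p >= p_min, , drop = FALSE]
  if (nrow(e) == 0L) return(e)
  sep <- e$j - e$i
  cap <- max(ceiling(stats::quantile(sep, 0.9, names = FALSE)), 5L)
  e[sep <= cap, , drop = FALSE]
}

#' Detect domain boundaries from a composite contact map
#'
#' Structural domains show up as dense diagonal blocks with few contacts
#' crossing the boundary. Boundaries are found by greedy recursive min-cut:
#' a candidate cut after residue `k` scores the cross-boundary contact
#' weight within a `min_domain`-residue window each side, normalised by the
#' within-side weight, `score(k) = 2 W_cross / (W_left + W_right)`; the
#' lowest-scoring cut (leftmost on ties) is accepted while its score is
#' below `threshold`, then each side is segmented recursively. Entries with
#' `p < p_min` are ignored, and scoring is restricted to the near-diagonal
#' separation range actually populated (90th percentile of separations) so
#' sparse long-range contacts do not dilute the statistic.
#'
#' @param map a `CompositeContactMap` with `L >= 2 * min_domain`.
#' @param min_domain minimum domain size in residues (default 100).
#' @param threshold acceptance threshold on the normalised cross score
#'   (default 0.02); uniform single-domain maps score well above it.
#' @param p_min probability floor (default 0.3).
#' @return A `DomainSegmentation`: list with sorted `boundaries` (global
#'   indices `k`, meaning a cut between `k` and `k + 1`) and `scores`.
#'   Zero boundaries is a valid result.
#' @export
detect_domain_boundaries <- function(map, min_domain = 100L, threshold = 0.02,
                                     p_min = 0.3) {
  min_domain <- as.integer(min_domain)
  if (map$L < 2L * min_domain)
    stop("map length ", map$L, " shorter than 2 * min_domain")
  e <- boundary_entries(map, p_min)
  boundaries <- integer(0); scores <- numeric(0)
  if (nrow(e) == 0L)
    return(structure(list(boundaries = boundaries, scores = scores),
                     class = "DomainSegmentation"))
  segments <- list(c(1L, map$L))
  while (length(segments) > 0L) {
    seg <- segments[[1]]; segments <- segments[-1]
    lo <- seg[1]; hi <- seg[2]
    ks <- seq.int(lo + min_domain - 1L, hi - min_domain)
    if (length(ks) == 0L || ks[1] > ks[length(ks)]) next
    sc <- vapply(ks, function(k) {
      wlo <- max(lo, k - min_domain + 1L); whi <- min(hi, k + min_domain)
      in_l <- e$i >= wlo & e$i <= k
      in_r_j <- e$j > k & e$j <= whi
      cross <- sum(e$p[in_l & in_r_j])
      wl <- sum(e$p[in_l & e$j <= k])
      wr <- sum(e$p[e$i > k & in_r_j])
      if (wl + wr == 0) return(1)      # featureless window: never cut
      2 * cross / (wl + wr)
    }, numeric(1))
    k_best <- ks[which.min(sc)]        # which.min takes the leftmost minimum
    s_best <- min(sc)
    if (s_best < threshold) {
      boundaries <- c(boundaries, k_best)
      scores <- c(scores, s_best)
      segments <- c(segments, list(c(lo, k_best)), list(c(k_best + 1L, hi)))
    }
  }
  ord <- order(boundaries)
  structure(list(boundaries = boundaries[ord], scores = scores[ord]),
            class = "DomainSegmentation")
}

#' @export
print.DomainSegmentation <- function(x, ...) {
  if (length(x$boundaries) == 0L) cat("DomainSegmentation: no boundaries\n")
  else cat("DomainSegmentation: boundaries at",
           paste(x$boundaries, collapse = ", "), "\n")
  invisible(x)
}

#' Detect tandem-repeat periodicity in a contact-map region
#'
#' Tandemly repeated structural units (the ~100-residue fibronectin-like
#' repeats, the 60-residue W units) give a contact pattern that recurs
#' along the sequence with the repeat period. The band-matrix rows within
#' `region` are column-centred (removing the generic near-diagonal
#' background) and the normalised autocorrelation along the position axis
#' is computed for lags `2..max_period`. To avoid reporting a harmonic, the
#' period is the smallest lag whose correlation reaches 90% of the peak.
#'
#' @param map a `CompositeContactMap`.
#' @param region `c(first, last)` global residue interval; its length must
#'   be at least `2 * max_period`.
#' @param max_period largest period considered, residues.
#' @param band band width for the underlying matrix (default 200).
#' @param p_min probability floor (default 0.3).
#' @return A `RepeatSignal`: list with `region`, `period`, `strength`
#'   (normalised autocorrelation at the reported period, in `[0, 1]`),
#'   `n_units` (`floor(region length / period)`), and `weak` (TRUE when
#'   `strength < 0.2`, i.e. no convincing periodicity).
#' @export
detect_repeat_period <- function(map, region, max_period, band = 200L, p_min = 0.3) {
  region <- as.integer(region); max_period <- as.integer(max_period)
  n <- region[2] - region[1] + 1L
  if (n < 2L * max_period)
    stop("region of ", n, " residues too short for max_period ", max_period)
  B <- render_diagonal_band(map, band)
  B[B < p_min] <- 0
  B <- B[region[1]:region[2], , drop = FALSE]
  Bc <- sweep(B, 2L, colMeans(B))
  lags <- 2L:max_period
  ac <- vapply(lags, function(l) {
    a <- Bc[1:(n - l), , drop = FALSE]
    b <- Bc[(l + 1L):n, , drop = FALSE]
    den <- sqrt(sum(a * a) * sum(b * b))
    if (den == 0) return(0)
    max(0, sum(a * b) / den)
  }, numeric(1))
  peak <- max(ac)
  if (peak <= 0) {
    period <- lags[1]; strength <- 0
  } else {
    period <- lags[ac >= 0.9 * peak][1]
    strength <- min(1, ac[match(period, lags)])
  }
  structure(list(region = region, period = as.integer(period),
                 strength = strength, n_units = n %/% period,
                 weak = strength < 0.2),
            class = "RepeatSignal")
}

#' @export
print.RepeatSignal <- function(x, ...) {
  cat(sprintf("RepeatSignal: region %d..%d, period %d (strength %.2f%s), %d units\n",
              x$region[1], x$region[2], x$period, x$strength,
              if (x$weak) ", WEAK" else "", x$n_units))
  invisible(x)
}
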