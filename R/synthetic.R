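#' Generate an ideal helical CA rod
#'
#' Deterministic CA trace on a helical curve: residue i sits at angle
#' `(i-1) * turn` on a circle of `radius`, raised by `rise` per residue.
#' The defaults (rise 1.5 A, turn 100 degrees, radius 2.3 A) approximate an
#' ideal alpha-helix; `radius = 0` gives a straight rod whose extent is
#' exactly `(n - 1) * rise`.
#'
#' @param n number of residues (>= 2).
#' @param rise axial rise per residue, Angstrom.
#' @param turn rotation per residue, degrees.
#' @param radius helix radius, Angstrom.
#' @param start_index residue number of the first residue.
#' @param model_id,scheme labels for the resulting `ChainModel`.
#' @return A `ChainModel` of poly-alanine.
#' @export
make_helix_rod <- function(n, rise = 1.5, turn = 100, radius = 2.3,
                           start_index = 1L, model_id = "helix_rod",
                           scheme = "MS22337_orf") {
  n <- as.integer(n)
  if (n < 2L) stop("n must be >= 2")
  i <- seq_len(n) - 1L
  theta <- i * turn * pi / 180
  ca <- cbind(radius * cos(theta), radius * sin(theta), i * rise)
  chain_model(model_id, scheme, start_index + i, rep("A", n), ca)
}

#' Perturb a model with Gaussian coordinate noise
#'
#' Adds i.i.d. `N(0, sigma^2)` noise to every coordinate component. The RNG
#' state is local to the call, so the output is a pure function of
#' `(model, sigma, seed)`. The expected (pre-superposition) RMSD to the
#' original is `sigma * sqrt(3)`.
#'
#' @param model a `ChainModel`.
#' @param sigma noise standard deviation per coordinate, Angstrom (>= 0).
#' @param seed integer seed.
#' @return The perturbed `ChainModel`.
#' @export
perturb_model <- function(model, sigma, seed) {
  stopifnot(sigma >= 0)
  if (sigma == 0) return(model)
  with_local_seed(seed, {
    noise <- matrix(stats::rnorm(3L * length(model), sd = sigma),
                    ncol = 3L)
    chain_model(model$model_id, model$scheme, model$seq_index, model$aa,
                model$ca + noise, model$extra_atoms)
  })
}

#' Apply a random rigid transform to a model
#'
#' Convenience for superposition fixtures: a uniformly random proper
#' rotation (QR of a Gaussian matrix, sign-fixed) plus a random translation.
#'
#' @param model a `ChainModel`.
#' @param seed integer seed.
#' @param max_translation translation components drawn from
#'   `U(-max_translation, max_translation)`.
#' @return list with `model` (transformed) and `transform` (the
#'   `RigidTransform` applied).
#' @export
random_rigid_move <- function(model, seed, max_translation = 20) {
  with_local_seed(seed, {
    Q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
    if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    tvec <- stats::runif(3, -max_translation, max_translation)
    tr <- rigid_transform(Q, tvec)
    list(model = chain_transform(model, tr), transform = tr)
  })
}

# truth contact density, fixed package-wide: dense short range within a
# domain, medium band to separation 12, repeat band 0.6, intra-unit motif 0.7
SYN_P_SHORT <- 0.9
SYN_P_MED <- 0.5
SYN_P_REPEAT <- 0.6
SYN_P_MOTIF <- 0.7

#' Synthetic segmented contact-map fixture with known truth
#'
#' Emulates a full-length predicted contact map for a multidomain protein
#' and its decomposition into overlapping prediction segments (the way
#' length-capped servers are fed, e.g. windows 1-799, 301-1099, 501-1299,
#' 926-1725 of the mature PrtP). Ground truth is planted: residue pairs
#' within the same domain get probability 0.9 (separation <= 4) or 0.5
#' (separation 5-12) with no cross-domain contacts; an optional repeat
#' region adds an inter-unit band at the planted period (p 0.6) plus a
#' per-fixture random intra-unit contact motif repeated identically in
#' every unit (p 0.7), which is what makes the periodicity detectable by
#' autocorrelation. `noise_frac` spurious contacts (p ~ U(0,1)) are
#' scattered uniformly.
#'
#' @param L full sequence length.
#' @param boundaries planted domain boundaries (cut after these indices).
#' @param repeat_spec optional `list(region = c(a, b), period = P)`.
#' @param segment_scheme list of `c(offset, length)` segment windows; must
#'   jointly cover `1..L`.
#' @param noise_frac fraction of spurious contacts relative to the number
#'   of true contacts (default 0.1).
#' @param seed integer seed; the fixture is a pure function of
#'   (parameters, seed).
#' @return list with `segments` (list of `SegmentContactMap`) and `truth`
#'   (a `FixtureTruth` record of everything planted).
#' @export
make_segmented_contact_fixture <- function(L, boundaries = integer(0),
                                           repeat_spec = NULL,
                                           segment_scheme = list(c(1L, L)),
                                           noise_frac = 0.1, seed = 1L) {
  L <- as.integer(L)
  segs <- lapply(segment_scheme, as.integer)
  cov <- rep(FALSE, L)
  for (s in segs) {
    if (s[1] < 1L || s[1] + s[2] - 1L > L)
      stop("segment ", s[1], "..", s[1] + s[2] - 1L, " outside 1..", L)
    cov[s[1]:(s[1] + s[2] - 1L)] <- TRUE
  }
  if (!all(cov))
    stop("segments do not cover the full sequence (first uncovered position ",
         which(!cov)[1], ")")
  domain_of <- findInterval(seq_len(L), c(1L, sort(as.integer(boundaries)) + 1L))

  with_local_seed(seed, {
    pieces <- vector("list", 12L)
    for (s in 1:12) {
      i <- seq_len(L - s); j <- i + s
      same <- domain_of[i] == domain_of[j]
      p <- if (s <= 4L) SYN_P_SHORT else SYN_P_MED
      pieces[[s]] <- data.frame(i = i[same], j = j[same], p = p)
    }
    truth <- do.call(rbind, pieces)
    motif <- NULL
    if (!is.null(repeat_spec)) {
      a <- as.integer(repeat_spec$region[1]); b <- as.integer(repeat_spec$region[2])
      P <- as.integer(repeat_spec$period)
      ib <- a:(b - P)
      truth <- rbind(truth, data.frame(i = ib, j = ib + P, p = SYN_P_REPEAT))
      n_motif <- 25L
      da <- sample.int(P - 18L, n_motif, replace = TRUE) - 1L
      room <- P - 1L - (da + 13L)
      db <- da + 13L + floor(stats::runif(n_motif) * (room + 1))
      starts <- seq.int(a, b - P + 1L, by = P)
      motif <- data.frame(da = da, db = db)
      for (u in starts) {
        ii <- u + da; jj <- u + db
        ok <- jj <= b
        truth <- rbind(truth, data.frame(i = ii[ok], j = jj[ok], p = SYN_P_MOTIF))
      }
    }
    n_noise <- round(noise_frac * nrow(truth))
    if (n_noise > 0L) {
      ni <- sample.int(L, n_noise, replace = TRUE)
      nj <- sample.int(L, n_noise, replace = TRUE)
      ok <- ni != nj
      noise <- data.frame(i = pmin(ni, nj)[ok], j = pmax(ni, nj)[ok],
                          p = stats::runif(sum(ok)))
      truth <- rbind(truth, noise)
    }
    dt <- data.table::data.table(truth)
    dt <- dt[, list(p = max(p)), by = c("i", "j")]
    full <- as.data.frame(dt)

    segments <- lapply(segs, function(s) {
      lo <- s[1]; hi <- s[1] + s[2] - 1L
      e <- full[full$i >= lo & full$j <= hi, , drop = FALSE]
      segment_contact_map(lo, s[2],
                          data.frame(i = e$i - lo + 1L, j = e$j - lo + 1L, p = e$p))
    })
    truth_rec <- structure(
      list(L = L, boundaries = sort(as.integer(boundaries)),
           repeat_spec = repeat_spec, motif = motif,
           segment_scheme = segs, noise_frac = noise_frac,
           n_contacts = nrow(full), seed = as.integer(seed)),
      class = "FixtureTruth")
    list(segments = segments, truth = truth_rec)
  })
}

#' Synthetic catalytic-triad model with planted state
#'
#' Builds a small CA chain embedding residues numbered 215 (Asp), 279 (His)
#' and 618 (Ser) with planted geometry mirroring the two states seen across
#' PrtP model ensembles: the Asp-Ser distance is fixed at 7 A; the His-Ser
#' distance is drawn uniformly in 5-7 A (assembled) or 14-19 A (displaced),
#' with the His placed so an assembled triad also keeps Asp-His within
#' 10 A. Flanking residues form short helical stubs so the chain is a valid
#' (if minimal) structure.
#'
#' @param state `"assembled"` or `"displaced"`.
#' @param seed integer seed.
#' @param model_id label (default derived from state and seed).
#' @return list with `model` (a `ChainModel`) and `truth` (a `FixtureTruth`
#'   with the planted distances and intended state).
#' @export
make_triad_fixture <- function(state = c("assembled", "displaced"), seed = 1L,
                               model_id = NULL) {
  state <- match.arg(state)
  if (is.null(model_id)) model_id <- sprintf("synthetic_triad_%s_%d", state, seed)
  with_local_seed(seed, {
    h_s <- if (state == "assembled") stats::runif(1, 5, 7) else stats::runif(1, 14, 19)
    phi <- stats::runif(1, 90, 150) * pi / 180
    d_xyz <- c(0, 0, 0)
    s_xyz <- c(7, 0, 0)
    h_xyz <- s_xyz + h_s * c(cos(phi), sin(phi), 0)

    blocks <- list(c(210L, 220L), c(275L, 283L), c(614L, 622L))
    centers <- list(c(0, -12, 0), c(14, 14, 6), c(7, -4, 12))
    seq_index <- integer(0); ca <- NULL
    for (k in seq_along(blocks)) {
      rng <- blocks[[k]]; nb <- rng[2] - rng[1] + 1L
      stub <- make_helix_rod(nb, start_index = rng[1])$ca
      stub <- sweep(stub, 2L, colMeans(stub))
      stub <- sweep(stub, 2L, centers[[k]], "+")
      seq_index <- c(seq_index, rng[1]:rng[2])
      ca <- rbind(ca, stub)
    }
    ca[match(215L, seq_index), ] <- d_xyz
    ca[match(279L, seq_index), ] <- h_xyz
    ca[match(618L, seq_index), ] <- s_xyz
    aa <- rep("A", length(seq_index))
    aa[match(c(215L, 279L, 618L), seq_index)] <- c("D", "H", "S")
    model <- chain_model(model_id, "MS22337_orf", seq_index, aa, ca)
    truth <- structure(list(state = state, d_s = 7, h_s = h_s,
                            triad_xyz = rbind(D = d_xyz, H = h_xyz, S = s_xyz),
                            seed = as.integer(seed)),
                       class = "FixtureTruth")
    list(model = model, truth = truth)
  })
}

#' Synthetic PrtP-like open reading frame
#'
#' Random protein ORF mimicking the coordinate layout of the MS22337 PrtP:
#' a propeptide region, then a mature protein of `mature_length` residues
#' beginning `"DAK"` at `mature_start` and ending with the cell-wall
#' coupling motif `"PKT"`, followed by an anchor tail guaranteed free of
#' further motif occurrences. This is a labelled synthetic stand-in for the
#' real ORF translation (which must be fetched from GenBank); it exercises
#' the mature-sequence extraction logic with planted truth.
#'
#' @param seed integer seed.
#' @param orf_length total ORF length (default 1962).
#' @param mature_start position of the mature N-terminal aspartate
#'   (default 186).
#' @param mature_length planted mature-protein length (default 1725).
#' @param id sequence label.
#' @return A `SequenceRecord`.
#' @export
make_synthetic_orf <- function(seed = 1L, orf_length = 1962L, mature_start = 186L,
                               mature_length = 1725L, id = "synthetic_MS22337_like") {
  orf_length <- as.integer(orf_length)
  mature_start <- as.integer(mature_start)
  mature_end <- mature_start + as.integer(mature_length) - 1L
  stopifnot(mature_end <= orf_length, mature_start > 3L)
  with_local_seed(seed, {
    chars <- sample(AA_ALPHABET, orf_length, replace = TRUE)
    chars[mature_start:(mature_start + 2L)] <- c("D", "A", "K")
    chars[(mature_end - 2L):mature_end] <- c("P", "K", "T")
    s <- paste(chars, collapse = "")
    # scrub accidental PKT occurrences after the planted terminal motif
    repeat {
      hits <- gregexpr("PKT", s, fixed = TRUE)[[1]]
      hits <- hits[hits > mature_end - 2L]
      if (length(hits) == 0L || hits[1] == -1L) break
      substr(s, hits[1], hits[1]) <- "G"
    }
    sequence_record(id, s)
  })
}

#' Substitute residues at random positions
#'
#' Plants an exact Hamming distance: `n_substitutions` distinct positions
#' are each changed to a different residue, so the pairwise difference
#' count between input and output (gap-free) is exactly `n_substitutions`.
#' Used to build synthetic strain families with known pairwise difference
#' counts.
#'
#' @param record a `SequenceRecord` without gaps.
#' @param n_substitutions number of positions to change.
#' @param seed integer seed.
#' @param id label for the mutant (default derived).
#' @return A `SequenceRecord`.
#' @export
mutate_sequence <- function(record, n_substitutions, seed, id = NULL) {
  chars <- strsplit(record$residues, "")[[1]]
  if (any(chars == "-")) stop("mutate_sequence expects an ungapped sequence")
  if (is.null(id)) id <- sprintf("%s_mut%d_s%d", record$id, n_substitutions, seed)
  with_local_seed(seed, {
    pos <- sample.int(length(chars), n_substitutions)
    for (p in pos) chars[p] <- sample(setdiff(AA_ALPHABET, chars[p]), 1L)
    sequence_record(id, paste(chars, collapse = ""))
  })
}

#' Write a fixture truth record as a TSV sidecar
#'
#' @param truth a `FixtureTruth`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_fixture_truth <- function(truth, path) {
  flat <- lapply(truth, function(v) {
    if (is.null(v)) "NA"
    else if (is.data.frame(v) || is.matrix(v))
      paste(apply(as.matrix(v), 1L, paste, collapse = ","), collapse = ";")
    else if (is.list(v)) paste(vapply(v, function(x) paste(unlist(x), collapse = ","),
                                      character(1)), collapse = ";")
    else paste(v, collapse = ",")
  })
  utils::write.table(data.frame(key = names(flat), value = unlist(flat)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
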