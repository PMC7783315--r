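#' Residue coordinate schemes for PrtP
#'
#' The literature on the lactococcal cell-envelope proteinase mixes residue
#' numbering schemes: counting from the start of the open reading frame
#' (MS22337 ORF), from the mature N-terminus (the aspartate D186 of the ORF
#' is mature residue 1), SK11 mature numbering, and the composite contact
#' map frame (also relative to the mature N-terminus). Every scheme is a
#' pure offset against the ORF frame: `orf = pos + offset_to_orf`.
#'
#' @return Named integer vector of `offset_to_orf` values.
#' @export
coordinate_schemes <- function() {
  c(MS22337_orf = 0L, MS22337_mature = 185L, SK11_mature = 185L, fig1_map = 185L)
}

#' Map a residue position between coordinate schemes
#'
#' Pure offset translation; e.g. SK11 mature 433 is MS22337 ORF 618 (the
#' catalytic serine) and SK11 mature 748 is ORF 933 under the default
#' +185 offset. Published conversions are internally inconsistent by one
#' residue in places, so the per-scheme offset can be overridden per call.
#'
#' @param pos residue position (>= 1) in the source scheme.
#' @param from,to scheme tags from [coordinate_schemes()].
#' @param from_offset,to_offset optional overrides of the schemes'
#'   `offset_to_orf` values.
#' @return Integer position in the target scheme.
#' @export
map_coordinates <- function(pos, from, to, from_offset = NULL, to_offset = NULL) {
  off <- coordinate_schemes()
  if (is.null(from_offset)) {
    if (!from %in% names(off)) stop("unknown scheme: ", from)
    from_offset <- off[[from]]
  }
  if (is.null(to_offset)) {
    if (!to %in% names(off)) stop("unknown scheme: ", to)
    to_offset <- off[[to]]
  }
  pos <- as.integer(pos)
  if (any(pos < 1L)) stop("positions must be >= 1")
  out <- pos + as.integer(from_offset) - as.integer(to_offset)
  if (any(out < 1L))
    stop("position ", pos[out < 1L][1], " maps below 1 in scheme '", to, "'")
  out
}

#' PrtP domain annotation
#'
#' Named domain intervals of the MS22337 PrtP in ORF numbering, following
#' the standard PP/PR/A/B/H/W nomenclature for lactococcal cell-envelope
#' proteinases: propeptide (PP), subtilisin-family proteinase core (PR,
#' which contains the catalytic triad D215/H279/S618), the fibronectin-like
#' A+B stalk, the helical domain H, and the cell-wall W domain built from
#' 60-residue repeat units between H and the membrane anchor.
#'
#' @param n_w_repeats number of 60-residue W units (strains carry 1 to 3).
#' @return data.frame with columns `domain`, `start`, `end` (ORF numbering).
#' @export
prtp_domains <- function(n_w_repeats = 2) {
  w_start <- 1801L
  w_end <- w_start + as.integer(round(n_w_repeats * 60)) - 1L
  data.frame(
    domain = c("PP", "PR", "AB", "H", "W", "AN"),
    start = c(32L, 186L, 699L, 1570L, w_start, w_end + 1L),
    end = c(185L, 698L, 1574L, 1800L, w_end, w_end + 35L),
    stringsAsFactors = FALSE)
}

#' Catalytic-triad specification
#'
#' @param d_index,h_index,s_index residue numbers of the aspartate,
#'   histidine and serine (defaults: D215, H279, S618 of the MS22337 ORF).
#' @param atom_rule `"CA"` (default) or `"functional_atom"` (OG for Ser,
#'   NE2 for His, CG for Asp, falling back to CA when the atom is absent).
#' @param scheme coordinate scheme the indices refer to.
#' @return An object of class `TriadSpec`.
#' @export
triad_spec <- function(d_index = 215L, h_index = 279L, s_index = 618L,
                       atom_rule = c("CA", "functional_atom"),
                       scheme = "MS22337_orf") {
  atom_rule <- match.arg(atom_rule)
  idx <- as.integer(c(d_index, h_index, s_index))
  if (anyDuplicated(idx)) stop("triad residue indices must be distinct")
  structure(list(d_index = idx[1], h_index = idx[2], s_index = idx[3],
                 atom_rule = atom_rule, scheme = scheme),
            class = "TriadSpec")
}

FUNCTIONAL_ATOM <- c(D = "CG", H = "NE2", S = "OG")

triad_atom_xyz <- function(model, seq_index, role, atom_rule) {
  pos <- match(seq_index, model$seq_index)
  if (is.na(pos))
    stop("residue ", seq_index, " missing from model '", model$model_id, "'")
  if (atom_rule == "functional_atom" && !is.null(model$extra_atoms)) {
    want <- FUNCTIONAL_ATOM[[role]]
    hit <- model$extra_atoms$seq_index == seq_index & model$extra_atoms$atom == want
    if (any(hit)) {
      row <- model$extra_atoms[which(hit)[1], ]
      return(c(row$x, row$y, row$z))
    }
  }
  model$ca[pos, ]
}

#' Measure catalytic-triad geometry
#'
#' The three pairwise distances among the Asp/His/Ser of a subtilisin-type
#' catalytic triad. In a catalytically competent arrangement all three
#' cluster within a few Angstrom (the PrtP models place Ser 7 A from Asp,
#' with His about 6 A from both); in "displaced" models the histidine sits
#' 15-18 A from the serine.
#'
#' @param model a `ChainModel` containing all three residues.
#' @param spec a [triad_spec()].
#' @return A `TriadGeometry`: list with `d_s`, `d_h`, `h_s` distances
#'   (Angstrom) and `model_id`.
#' @export
triad_distances <- function(model, spec = triad_spec()) {
  d <- triad_atom_xyz(model, spec$d_index, "D", spec$atom_rule)
  h <- triad_atom_xyz(model, spec$h_index, "H", spec$atom_rule)
  s <- triad_atom_xyz(model, spec$s_index, "S", spec$atom_rule)
  structure(list(d_s = sqrt(sum((d - s)^2)),
                 d_h = sqrt(sum((d - h)^2)),
                 h_s = sqrt(sum((h - s)^2)),
                 model_id = model$model_id),
            class = "TriadGeometry")
}

#' Classify a triad as assembled or displaced
#'
#' The catalytic state is determined solely by how far the histidine sits
#' from its two partners: assembled when `max(d_h, h_s) <= threshold`. The
#' default threshold of 10 A is the midpoint between the ~6 A histidine
#' separation of assembled models and the 15-18 A of displaced ones. The
#' boundary case equal to the threshold classifies as assembled.
#'
#' @param geom a `TriadGeometry`.
#' @param threshold classification threshold, Angstrom (default 10).
#' @return A `TriadState`: list with `state` (`"assembled"`/`"displaced"`)
#'   and signed `margin` (`threshold - max(d_h, h_s)`; positive means
#'   assembled with room to spare).
#' @export
classify_triad <- function(geom, threshold = 10) {
  worst <- max(geom$d_h, geom$h_s)
  structure(list(state = if (worst <= threshold) "assembled" else "displaced",
                 margin = threshold - worst),
            class = "TriadState")
}

#' CA-CA distance between two residues
#'
#' @param model a `ChainModel`.
#' @param i,j residue numbers (model scheme).
#' @return Euclidean distance in Angstrom.
#' @export
residue_pair_distance <- function(model, i, j) {
  pi_ <- match(as.integer(i), model$seq_index)
  pj_ <- match(as.integer(j), model$seq_index)
  if (is.na(pi_)) stop("residue ", i, " missing from model '", model$model_id, "'")
  if (is.na(pj_)) stop("residue ", j, " missing from model '", model$model_id, "'")
  sqrt(sum((model$ca[pi_, ] - model$ca[pj_, ])^2))
}

#' Triad geometry and state across a model ensemble
#'
#' One row per model with the three triad distances, the assembled /
#' displaced call and its margin. A model missing a triad residue yields a
#' row of missing values rather than aborting the ensemble. Summary counts
#' per state are attached as the `"summary"` attribute.
#'
#' @param models list of `ChainModel`s.
#' @param spec a [triad_spec()].
#' @param threshold classification threshold, Angstrom.
#' @return data.frame (`model_id`, `d_s`, `d_h`, `h_s`, `state`, `margin`)
#'   with attribute `summary` = named counts of assembled / displaced /
#'   missing.
#' @export
ensemble_triad_report <- function(models, spec = triad_spec(), threshold = 10) {
  stopifnot(length(models) >= 1L)
  rows <- lapply(models, function(m) {
    geom <- tryCatch(triad_distances(m, spec), error = function(e) NULL)
    if (is.null(geom))
      return(data.frame(model_id = m$model_id, d_s = NA_real_, d_h = NA_real_,
                        h_s = NA_real_, state = NA_character_,
                        margin = NA_real_, stringsAsFactors = FALSE))
    st <- classify_triad(geom, threshold)
    data.frame(model_id = m$model_id, d_s = geom$d_s, d_h = geom$d_h,
               h_s = geom$h_s, state = st$state, margin = st$margin,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "summary") <- c(assembled = sum(out$state == "assembled", na.rm = TRUE),
                            displaced = sum(out$state == "displaced", na.rm = TRUE),
                            missing = sum(is.na(out$state)))
  out
}

#' Molecular extent along the principal axis
#'
#' Length of the CA-coordinate projection range along the first principal
#' axis: the "height" of an elongated molecule such as the PrtP stalk.
#' Invariant under rigid transforms.
#'
#' @param model a `ChainModel` with at least 2 residues.
#' @return Extent in Angstrom.
#' @export
estimate_extent <- function(model) {
  if (length(model) < 2L) stop("need at least 2 residues")
  xc <- sweep(model$ca, 2L, colMeans(model$ca))
  if (max(abs(xc)) < 1e-9) stop("degenerate model: all coordinates identical")
  ax <- svd(xc, nu = 0, nv = 1)$v[, 1]
  proj <- xc %*% ax
  diff(range(proj))
}

# rotation taking unit vector a onto unit vector b (Rodrigues)
rotation_between <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  c_ <- sum(a * b)
  if (abs(c_ + 1) < 1e-12) {           # antiparallel: rotate pi about any perpendicular
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- p - sum(p * a) * a; v <- v / sqrt(sum(v^2))
    return(2 * outer(v, v) - diag(3))
  }
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx / (1 + c_)
}

#' Naive axial assembly of domain models
#'
#' Stacks individually modelled domains along the global z-axis: each
#' domain is rotated so its first principal axis lies on z (oriented
#' N-to-C upward), then placed above the previous domain with `gap`
#' Angstrom of axial spacing. This is a deliberately simple stand-in for
#' physically docking domains - it estimates overall molecular dimensions,
#' nothing more. No clash checking beyond the inter-domain gap is done.
#'
#' @param domains ordered list of `ChainModel`s with non-overlapping,
#'   increasing residue ranges.
#' @param gap axial spacing between consecutive domains, Angstrom.
#' @return A single `ChainModel` spanning all input residue ranges.
#' @export
assemble_domains <- function(domains, gap = 3) {
  stopifnot(length(domains) >= 1L)
  last_end <- -Inf
  for (d in domains) {
    if (min(d$seq_index) <= last_end)
      stop("domain residue ranges must be non-overlapping and in order")
    last_end <- max(d$seq_index)
  }
  z_top <- 0
  placed <- lapply(domains, function(d) {
    xc <- sweep(d$ca, 2L, colMeans(d$ca))
    ax <- svd(xc, nu = 0, nv = 1)$v[, 1]
    nc <- d$ca[nrow(d$ca), ] - d$ca[1, ]        # orient N -> C along +z
    if (sum(nc * ax) < 0) ax <- -ax
    R <- rotation_between(ax, c(0, 0, 1))
    xyz <- xc %*% t(R)
    shift <- z_top - min(xyz[, 3])
    xyz[, 3] <- xyz[, 3] + shift
    z_top <<- max(xyz[, 3]) + gap
    tr <- rigid_transform(R, c(0, 0, 0))
    extra <- d$extra_atoms
    if (!is.null(extra)) {
      exyz <- sweep(as.matrix(extra[, c("x", "y", "z")]), 2L, colMeans(d$ca)) %*% t(R)
      exyz[, 3] <- exyz[, 3] + shift
      extra[, c("x", "y", "z")] <- exyz
    }
    list(seq_index = d$seq_index, aa = d$aa, ca = xyz, extra = extra)
  })
  extra_all <- do.call(rbind, Filter(Negate(is.null), lapply(placed, `[[`, "extra")))
  chain_model(domains[[1]]$model_id, domains[[1]]$scheme,
              unlist(lapply(placed, `[[`, "seq_index")),
              unlist(lapply(placed, `[[`, "aa")),
              do.call(rbind, lapply(placed, `[[`, "ca")),
              extra_all)
}
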