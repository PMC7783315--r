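#' Read a protein chain from a PDB file
#'
#' Parses a PDB-format file (via bio3d) and returns the first chain (or a
#' requested chain) as a [chain_model()]. Residue numbers are taken verbatim
#' from the file; no renumbering is performed, so the caller declares which
#' coordinate scheme the file uses. Every residue must carry a CA atom.
#' Alternate locations other than blank or 'A' are dropped; insertion codes
#' are rejected because predicted models do not use them and silently
#' renumbering would corrupt scheme bookkeeping.
#'
#' @param path path to a PDB file.
#' @param model_id label for the resulting model; defaults to the file name.
#' @param scheme coordinate-scheme tag (see [coordinate_schemes()]).
#' @param chain optional chain identifier; default takes the first chain.
#' @return A `ChainModel`. Non-CA heavy atoms of the selected chain are kept
#'   in `extra_atoms` so side-chain distance rules remain available.
#' @export
read_structure <- function(path, model_id = basename(path), scheme = "MS22337_orf",
                           chain = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE),
                  error = function(e) stop("unparsable PDB file '", path, "': ",
                                           conditionMessage(e)))
  atoms <- pdb$atom
  atoms <- atoms[atoms$type == "ATOM", , drop = FALSE]
  if (nrow(atoms) == 0L) stop("no ATOM records in ", path)
  if (is.null(chain)) chain <- atoms$chain[1]
  atoms <- atoms[is.na(atoms$chain) | atoms$chain == chain, , drop = FALSE]
  if (nrow(atoms) == 0L) stop("chain '", chain, "' not found in ", path)
  ins <- atoms$insert
  if (any(!is.na(ins) & ins != ""))
    stop("insertion codes are not supported (first at residue ",
         atoms$resno[which(!is.na(ins) & ins != "")[1]], ")")
  alt <- atoms$alt
  atoms <- atoms[is.na(alt) | alt %in% c("", "A"), , drop = FALSE]

  ca <- atoms[atoms$elety == "CA", , drop = FALSE]
  resno_all <- unique(atoms$resno)
  missing_ca <- setdiff(resno_all, ca$resno)
  if (length(missing_ca) > 0L)
    stop("residue ", missing_ca[1], " has no CA atom in ", path)
  if (anyDuplicated(ca$resno))
    stop("duplicated residue number ", ca$resno[duplicated(ca$resno)][1],
         " in ", path)
  ord <- order(ca$resno)
  ca <- ca[ord, , drop = FALSE]
  aa <- bio3d::aa321(ca$resid)
  aa[is.na(aa) | !aa %in% c(AA_ALPHABET, "X")] <- "X"

  other <- atoms[atoms$elety != "CA", , drop = FALSE]
  extra <- NULL
  if (nrow(other) > 0L) {
    extra <- data.frame(seq_index = other$resno, atom = other$elety,
                        x = other$x, y = other$y, z = other$z,
                        stringsAsFactors = FALSE)
  }
  chain_model(model_id, scheme, ca$resno, aa,
              cbind(ca$x, ca$y, ca$z), extra)
}

#' Write a ChainModel to a PDB file
#'
#' Emits one ATOM record per CA (plus any extra atoms), occupancy 1.00,
#' B-factor 0.00, followed by TER and END. Coordinates are written at PDB
#' precision (3 decimals), which bounds round-trip fidelity.
#'
#' @param model a `ChainModel` with at least one residue.
#' @param path output file path.
#' @param chain chain identifier to write (default `"A"`).
#' @return Invisibly, `path`.
#' @export
write_structure <- function(model, path, chain = "A") {
  if (!inherits(model, "ChainModel")) stop("model must be a ChainModel")
  n <- length(model$seq_index)
  if (n == 0L) stop("refusing to write an empty model")
  resno <- model$seq_index
  resid3 <- ifelse(model$aa == "X", "UNK", bio3d::aa123(model$aa))
  rec <- character(0)
  serial <- 0L
  extra <- model$extra_atoms
  for (k in seq_len(n)) {
    serial <- serial + 1L
    rec <- c(rec, pdb_atom_line(serial, "CA", resid3[k], chain, resno[k],
                                model$ca[k, ]))
    if (!is.null(extra)) {
      ek <- extra[extra$seq_index == resno[k], , drop = FALSE]
      for (j in seq_len(nrow(ek))) {
        serial <- serial + 1L
        rec <- c(rec, pdb_atom_line(serial, ek$atom[j], resid3[k], chain,
                                    resno[k], c(ek$x[j], ek$y[j], ek$z[j])))
      }
    }
  }
  rec <- c(rec, sprintf("TER   %5d      %3s %s%4d", serial + 1L,
                        resid3[n], chain, resno[n]), "END")
  writeLines(rec, path)
  invisible(path)
}

pdb_atom_line <- function(serial, elety, resid, chain, resno, xyz) {
  name <- if (nchar(elety) < 4L) sprintf(" %-3s", elety) else elety
  elem <- substr(gsub("[0-9]", "", elety), 1, 1)
  sprintf("ATOM  %5d %4s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name, resid, chain, resno, xyz[1], xyz[2], xyz[3],
          1.00, 0.00, elem)
}

#' Write an ensemble as a multi-model PDB
#'
#' Each chain is wrapped in MODEL/ENDMDL records, the convention for
#' superposed ensembles.
#'
#' @param models list of `ChainModel`s.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_ensemble <- function(models, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(models)) {
    tmp <- tempfile(fileext = ".pdb")
    write_structure(models[[k]], tmp)
    lines <- readLines(tmp)
    unlink(tmp)
    lines <- lines[lines != "END"]
    writeLines(c(sprintf("MODEL     %4d", k), lines, "ENDMDL"), con)
  }
  writeLines("END", con)
  invisible(path)
}

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Construct a sequence record
#'
#' @param id sequence label.
#' @param residues amino-acid string; may contain `-` gaps when taken from an
#'   alignment and `X` for unknown residues.
#' @return An object of class `SequenceRecord`.
#' @export
sequence_record <- function(id, residues) {
  residues <- toupper(paste(residues, collapse = ""))
  chars <- strsplit(residues, "")[[1]]
  bad <- setdiff(unique(chars), c(AA_ALPHABET, "X", "-"))
  if (length(bad) > 0L)
    stop("invalid residue symbol(s): ", paste(bad, collapse = ", "))
  structure(list(id = as.character(id)[1], residues = residues),
            class = "SequenceRecord")
}

#' @export
print.SequenceRecord <- function(x, ...) {
  cat(sprintf("SequenceRecord '%s': %d characters\n", x$id, nchar(x$residues)))
  invisible(x)
}

#' Read sequences (or an alignment) from a FASTA file
#'
#' Aligned FASTA is simply FASTA whose records have equal length and may
#' contain gaps.
#'
#' @param path path to a FASTA file.
#' @return Named list of `SequenceRecord`s.
#' @export
read_fasta_records <- function(path) {
  aln <- bio3d::read.fasta(path, rm.dup = FALSE)
  ids <- rownames(aln$ali)
  out <- lapply(seq_along(ids), function(k) {
    sequence_record(ids[k], paste(aln$ali[k, ], collapse = ""))
  })
  names(out) <- ids
  out
}

#' Extract the mature protein sequence
#'
#' The mature lactococcal cell-envelope proteinase begins where the
#' propeptide is autocatalytically removed (the aspartate written D186 in the
#' MS22337 open reading frame, sequence starting "DAK") and ends with the
#' C-terminal motif covalently coupled to the peptidoglycan (the "PKT"
#' sortase-processing region). This helper cuts that span out of a full ORF
#' translation: gaps are removed first, then the subsequence from
#' `start_index` through the end of the LAST occurrence of `end_motif` is
#' returned.
#'
#' @param seq a `SequenceRecord` (gaps allowed; removed before indexing).
#' @param start_index 1-based position of the mature N-terminus in the
#'   degapped sequence.
#' @param end_motif short amino-acid motif whose last occurrence terminates
#'   the mature protein.
#' @return A `SequenceRecord` holding the mature subsequence.
#' @export
extract_mature_sequence <- function(seq, start_index, end_motif) {
  degapped <- gsub("-", "", seq$residues, fixed = TRUE)
  n <- nchar(degapped)
  start_index <- as.integer(start_index)
  if (start_index < 1L || start_index > n)
    stop("start_index ", start_index, " outside sequence of length ", n)
  hits <- gregexpr(end_motif, degapped, fixed = TRUE)[[1]]
  hits <- hits[hits >= start_index]
  if (length(hits) == 0L || hits[1] == -1L)
    stop("end motif '", end_motif, "' not found at or after position ", start_index)
  stop_at <- max(hits) + nchar(end_motif) - 1L
  sequence_record(paste0(seq$id, "_mature"),
                  substr(degapped, start_index, stop_at))
}

#' Count substitutions between two aligned sequences
#'
#' Column-wise difference count over an aligned pair, as used to compare
#' PrtP sequences between strains. With the default
#' `gap_policy = "ignore_gap_columns"` any column containing a gap in either
#' record is dropped before counting, so indels (such as the 2-aa propeptide
#' deletion) are not counted as substitutions; `"count_gaps"` counts every
#' differing column including gap-vs-residue.
#'
#' @param a,b `SequenceRecord`s of equal (aligned) length.
#' @param gap_policy `"ignore_gap_columns"` (default) or `"count_gaps"`.
#' @param window optional `c(first, last)` alignment-column window to
#'   restrict the count (e.g. the first 1800 columns).
#' @return Integer number of differing columns.
#' @export
count_sequence_differences <- function(a, b,
                                       gap_policy = c("ignore_gap_columns", "count_gaps"),
                                       window = NULL) {
  gap_policy <- match.arg(gap_policy)
  ca <- strsplit(a$residues, "")[[1]]
  cb <- strsplit(b$residues, "")[[1]]
  if (length(ca) != length(cb))
    stop("sequences must be aligned to equal length (", length(ca), " vs ",
         length(cb), ")")
  if (!is.null(window)) {
    idx <- max(1L, window[1]):min(length(ca), window[2])
    ca <- ca[idx]; cb <- cb[idx]
  }
  if (gap_policy == "ignore_gap_columns") {
    keep <- ca != "-" & cb != "-"
    ca <- ca[keep]; cb <- cb[keep]
  }
  sum(ca != cb)
}

#' Pair residues shared by two models
#'
#' Pairing is by identical residue number (both models must use the same
#' coordinate scheme); this is the "shared residues" notion used when
#' comparing predicted models that cover different spans of the same
#' sequence. Structure-based alignment is deliberately not attempted.
#'
#' @param a,b `ChainModel`s in the same scheme.
#' @param window optional `c(first, last)` residue-number window.
#' @return A two-column integer matrix (`index_a`, `index_b`) of positional
#'   indices into each model's residue list, sorted by residue number; zero
#'   rows when nothing is shared.
#' @export
shared_residue_pairing <- function(a, b, window = NULL) {
  if (a$scheme != b$scheme)
    stop("models use different coordinate schemes ('", a$scheme, "' vs '",
         b$scheme, "'); map_coordinates first")
  shared <- intersect(a$seq_index, b$seq_index)
  if (!is.null(window)) shared <- shared[shared >= window[1] & shared <= window[2]]
  shared <- sort(shared)
  cbind(index_a = match(shared, a$seq_index),
        index_b = match(shared, b$seq_index))
}
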