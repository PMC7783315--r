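#' Read a pipeline configuration file
#'
#' Flat INI-style `key = value` text (comments `#`). Multi-valued keys are
#' comma-separated. Recognised keys:
#' \describe{
#'   \item{models, model_schemes}{input PDB paths and their coordinate
#'     scheme tags (one tag, or one per model).}
#'   \item{contact_files, contact_offsets, L}{per-segment contact maps,
#'     their global offsets, and the full sequence length.}
#'   \item{triad_d, triad_h, triad_s, triad_threshold}{catalytic-triad
#'     residue numbers (defaults 215/279/618) and classification threshold
#'     (default 10).}
#'   \item{merge_rule, p_threshold, boundary_threshold, min_domain}{contact
#'     stitching and segmentation parameters.}
#'   \item{window_start, window_end}{core-comparison window (default
#'     186-698).}
#'   \item{pair_distances}{optional residue pairs `i-j` (comma-separated)
#'     to measure on the reference model.}
#'   \item{allow_missing_contacts}{`true` to run structure-only stages when
#'     no contact files are given.}
#'   \item{seed, out_dir}{RNG seed and output directory.}
#' }
#'
#' @param path configuration file.
#' @return A named list of class `PipelineConfig`.
#' @export
read_pipeline_config <- function(path) {
  raw <- readLines(path)
  raw <- raw[!grepl("^\\s*(#|$)", raw)]
  kv <- regmatches(raw, regexec("^\\s*([A-Za-z_]+)\\s*=\\s*(.*?)\\s*$", raw))
  bad <- which(lengths(kv) != 3L)
  if (length(bad) > 0L) stop("malformed config line: ", raw[bad[1]])
  cfg <- stats::setNames(lapply(kv, `[[`, 3L), vapply(kv, `[[`, "", 2L))
  split_csv <- function(x) trimws(strsplit(x, ",")[[1]])
  defaults <- list(models = character(0), model_schemes = "MS22337_orf",
                   contact_files = character(0), contact_offsets = integer(0),
                   L = NA_integer_, triad_d = 215L, triad_h = 279L,
                   triad_s = 618L, triad_threshold = 10, merge_rule = "mean",
                   p_threshold = 0.3, boundary_threshold = 0.02,
                   min_domain = 100L, window_start = 186L, window_end = 698L,
                   pair_distances = character(0),
                   allow_missing_contacts = FALSE, seed = 1L, out_dir = ".")
  out <- defaults
  for (key in names(cfg)) {
    val <- cfg[[key]]
    out[[key]] <- switch(key,
      models = , model_schemes = , contact_files = ,
      pair_distances = split_csv(val),
      contact_offsets = as.integer(split_csv(val)),
      L = , triad_d = , triad_h = , triad_s = , min_domain = ,
      window_start = , window_end = , seed = as.integer(val),
      triad_threshold = , p_threshold = , boundary_threshold = as.numeric(val),
      allow_missing_contacts = tolower(val) %in% c("true", "1", "yes"),
      val)
  }
  missing <- out$models[!file.exists(out$models)]
  if (length(missing) > 0L) stop("model file not found: ", missing[1])
  missing <- out$contact_files[!file.exists(out$contact_files)]
  if (length(missing) > 0L) stop("contact file not found: ", missing[1])
  structure(out, class = "PipelineConfig")
}

# small deterministic string hash (djb2) for the run manifest
config_hash <- function(lines) {
  h <- 5381
  for (ch in utf8ToInt(paste(lines, collapse = "\n"))) {
    h <- (h * 33 + ch) %% 2^31
  }
  sprintf("%08x", h)
}

pipeline_log <- function(...) {
  message(format(Sys.time(), "[%Y-%m-%d %H:%M:%S] "), sprintf(...))
}

#' Run the full model-analysis pipeline
#'
#' Orchestrates the analysis end-to-end: stitch per-segment contact maps
#' into a composite and render its diagonal band; detect domain boundaries
#' and repeat periodicity; compare all structure models pairwise over the
#' core window and select the medoid reference; superpose every model onto
#' the reference; report catalytic-triad geometry and state per model; and
#' measure any requested residue-pair distances on the reference model.
#' All outputs are deterministic TSV/PDB files plus a manifest recording
#' the configuration hash, package version and seed (no timestamps, so
#' reruns are byte-identical). A stage failure aborts with the stage name;
#' outputs written so far are kept with a `.partial` suffix appended.
#'
#' @param config a `PipelineConfig` from [read_pipeline_config()], or a
#'   path to a configuration file.
#' @return Invisibly, a named list of result objects
#'   (`composite`, `segmentation`, `comparison`, `reference`,
#'   `triad_report`, `pair_distances`, `output_files`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "PipelineConfig"))
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  results <- list()
  stage <- "setup"
  emit <- function(name) { outputs <<- c(outputs, file.path(out_dir, name)); outputs[length(outputs)] }

  on_fail <- function(e) {
    for (f in outputs) if (file.exists(f)) file.rename(f, paste0(f, ".partial"))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  }
  tryCatch({
    if (length(config$contact_files) > 0L) {
      stage <- "stitch"
      pipeline_log("stitching %d contact segments", length(config$contact_files))
      segs <- mapply(load_contact_map, config$contact_files,
                     config$contact_offsets, SIMPLIFY = FALSE)
      composite <- stitch(segs, config$L, config$merge_rule)
      write_contact_map(composite, emit("composite_contacts.txt"))
      stage <- "band"
      band <- render_diagonal_band(composite, 200L)
      utils::write.table(band, emit("band_matrix.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      stage <- "domains"
      segm <- detect_domain_boundaries(composite, config$min_domain,
                                       config$boundary_threshold,
                                       config$p_threshold)
      utils::write.table(
        data.frame(boundary = segm$boundaries, score = segm$scores),
        emit("domain_boundaries.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
      results$composite <- composite
      results$segmentation <- segm
    } else if (!config$allow_missing_contacts) {
      stage <- "stitch"
      stop("no contact files configured (set allow_missing_contacts = true ",
           "to run structure-only stages)")
    } else {
      warning("no contact files configured; skipping contact stages")
    }

    models <- list()
    if (length(config$models) > 0L) {
      stage <- "read_models"
      schemes <- rep_len(config$model_schemes, length(config$models))
      models <- mapply(function(p, s) {
        read_structure(p, model_id = sub("\\.pdb$", "", basename(p)), scheme = s)
      }, config$models, schemes, SIMPLIFY = FALSE)
      names(models) <- vapply(models, function(m) m$model_id, character(1))
    }
    if (length(models) >= 2L) {
      stage <- "compare"
      pipeline_log("comparing %d models over window %d..%d", length(models),
                   config$window_start, config$window_end)
      cmp <- compare_all(models, c(config$window_start, config$window_end))
      write_comparison_matrix(cmp, emit("comparison_tm.tsv"), "tm")
      write_comparison_matrix(cmp, emit("comparison_rmsd.tsv"), "rmsd")
      write_comparison_matrix(cmp, emit("comparison_shared.tsv"), "shared")
      stage <- "reference"
      ref_id <- select_reference(cmp)
      writeLines(ref_id, emit("reference_model.txt"))
      stage <- "superpose"
      ref <- models[[ref_id]]
      superposed <- lapply(models, function(m) {
        if (identical(m$model_id, ref_id)) return(m)
        pr <- shared_residue_pairing(m, ref,
                                     c(config$window_start, config$window_end))
        if (nrow(pr) < 3L) return(m)
        fit <- kabsch_superpose(m$ca[pr[, 1], ], ref$ca[pr[, 2], ])
        chain_transform(m, fit$transform)
      })
      write_ensemble(superposed, emit("superposed_ensemble.pdb"))
      results$comparison <- cmp
      results$reference <- ref_id
    } else if (length(models) == 1L) {
      results$reference <- models[[1]]$model_id
    }
    if (length(models) >= 1L) {
      stage <- "triad"
      spec <- triad_spec(config$triad_d, config$triad_h, config$triad_s)
      rep_ <- ensemble_triad_report(models, spec, config$triad_threshold)
      utils::write.table(rep_, emit("triad_report.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      results$triad_report <- rep_
      if (length(config$pair_distances) > 0L && !is.null(results$reference)) {
        stage <- "distances"
        refm <- models[[results$reference]]
        prs <- strsplit(config$pair_distances, "-")
        dist_tab <- do.call(rbind, lapply(prs, function(pr) {
          i <- as.integer(pr[1]); j <- as.integer(pr[2])
          data.frame(model_id = refm$model_id, i = i, j = j,
                     distance = residue_pair_distance(refm, i, j))
        }))
        utils::write.table(dist_tab, emit("pair_distances.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        results$pair_distances <- dist_tab
      }
    }
    stage <- "manifest"
    cfg_lines <- vapply(names(unclass(config)), function(k) {
      sprintf("%s = %s", k, paste(config[[k]], collapse = ","))
    }, character(1))
    manifest <- c(sprintf("config_hash = %s", config_hash(cfg_lines)),
                  sprintf("cepstruct_version = %s",
                          as.character(utils::packageVersion("cepstruct"))),
                  sprintf("seed = %d", config$seed),
                  cfg_lines)
    writeLines(manifest, emit("manifest.txt"))
  }, error = on_fail)
  results$output_files <- outputs
  invisible(results)
}
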