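#' Run the full association-mapping pipeline
#'
#' Orchestrates the stages in fixed order: (optionally) simulate a cohort,
#' complement-code and scale it, train the Auto-Contractive Map, convert
#' weights to distances and link strengths, filter with the minimum
#' spanning tree, and export the semantic connectivity map.  Every artifact
#' is written under `out_dir` and listed in a JSON run manifest; matrices
#' and edge lists are deterministic given the inputs and seed.
#'
#' Exactly one of `input` (a raw marker CSV) and `design` (a
#' [cohort_design()] or a YAML design path) must be supplied.  A
#' non-converged training run is flagged in the manifest but still
#' exported.
#'
#' @param input Path to a raw marker CSV (columns `subject_id`,
#'   `phenotype`, the 11-marker panel).
#' @param design A `cohort_design`, or path to a design YAML, for
#'   simulation mode (requires `seed`).
#' @param out_dir Output directory, created if absent.
#' @param autocm An [autocm_config()].
#' @param formats Graph export formats (subset of
#'   `c("graphml", "dot", "edge-tsv")`).
#' @param seed Integer seed for cohort simulation.
#' @param quiet Suppress stage progress messages (sent to `stderr`).
#' @return The manifest, invisibly: named list of artifact paths plus
#'   `seed`, `converged`, `epochs_run` and package/R versions.
#' @export
run_pipeline <- function(input = NULL, design = NULL, out_dir,
                         autocm = autocm_config(),
                         formats = c("graphml", "dot", "edge-tsv"),
                         seed = NULL, quiet = FALSE) {
  if (is.null(input) == is.null(design)) {
    stop("supply exactly one of 'input' (raw CSV) or 'design' (simulation)",
         call. = FALSE)
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  say <- function(...) if (!quiet) message("[autocmap] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  artifacts <- list()

  if (!is.null(design)) {
    if (is.character(design)) design <- stage("design", read_design(design))
    if (is.null(seed)) stop("simulation mode requires a seed", call. = FALSE)
    say("simulate: drawing cohort (seed ", seed, ")")
    table <- stage("simulate", generate_cohort(design, seed = seed))
    artifacts$cohort_csv <- file.path(out_dir, "cohort.csv")
    utils::write.csv(table, artifacts$cohort_csv, row.names = FALSE,
                     fileEncoding = "UTF-8")
  } else {
    say("load: reading marker table from ", input)
    table <- stage("load", read_marker_table(input, require_panel = TRUE))
  }

  say("preprocess: complement-coded scaling")
  dataset <- stage("preprocess", assemble_dataset(table))
  artifacts$scaled_csv <- file.path(out_dir, "scaled.csv")
  artifacts$provenance_json <- file.path(out_dir, "scaled.provenance.json")
  stage("preprocess",
        write_scaled_dataset(dataset, artifacts$scaled_csv,
                             artifacts$provenance_json))

  say("train: AutoCM on ", nrow(dataset$records), " records x ",
      ncol(dataset$records), " variables")
  model <- stage("train", autocm_train(dataset, autocm))
  artifacts$model_json <- file.path(out_dir, "model.json")
  stage("train", write_autocm(model, artifacts$model_json))

  say("map: distances, link strengths, minimum spanning tree")
  d <- stage("map", autocm_distances(model))
  ls <- stage("map", link_strengths(model))
  artifacts$distances_csv <- file.path(out_dir, "distances.csv")
  artifacts$link_strengths_csv <- file.path(out_dir, "link_strengths.csv")
  utils::write.csv(as.data.frame(d), artifacts$distances_csv,
                   fileEncoding = "UTF-8")
  utils::write.csv(as.data.frame(ls), artifacts$link_strengths_csv,
                   fileEncoding = "UTF-8")
  map <- stage("map", connectivity_map(model))

  say("export: ", paste(formats, collapse = ", "))
  ext <- c("graphml" = "graphml", "dot" = "dot", "edge-tsv" = "tsv")
  for (f in formats) {
    key <- paste0("map_", gsub("-", "_", f))
    artifacts[[key]] <- file.path(out_dir, paste0("map.", ext[[f]]))
    stage("export", export_graph(map, artifacts[[key]], format = f))
  }
  artifacts$hubs_tsv <- file.path(out_dir, "hubs.tsv")
  utils::write.table(hub_scores(map), artifacts$hubs_tsv, sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")

  manifest <- list(
    package = "autocmap",
    package_version = as.character(utils::packageVersion("autocmap")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    mode = if (is.null(input)) "simulate" else "real-data",
    seed = seed,
    config = unclass(autocm),
    converged = model$converged,
    epochs_run = model$epochs_run,
    artifacts = artifacts)
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  manifest$artifacts$manifest_json <- manifest_path
  say("done: ", length(manifest$artifacts), " artifacts in ", out_dir)
  invisible(manifest)
}
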