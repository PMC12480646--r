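#' Run the full detection pipeline
#'
#' One call from inputs to decision-ready outputs: obtain a tally table
#' (either by simulating a run or by ingesting an existing TSV), fit the
#' cumulative-tail cutoffs and classify every tally, run control QC,
#' produce the replicate/matrix/seasonal summaries and per-(site, taxon)
#' action recommendations, and write everything alongside a provenance
#' record (threshold fractions, seed, package version, config digest) so
#' any output can be traced to the settings that produced it.
#'
#' @param config either a path to a JSON config file or a list with
#'   elements:
#'   \describe{
#'     \item{mode}{`"simulate"` or `"ingest"`.}
#'     \item{manifest}{path to a manifest JSON (or a `run_manifest`).}
#'     \item{tallies}{(ingest mode) path to a tally TSV.}
#'     \item{sim}{(simulate mode) list of [sim_params()] arguments.}
#'     \item{thresholds}{list with `drop_frac`, `low_frac`,
#'       `include_controls` (defaults 0.006, 0.010, FALSE).}
#'     \item{seed}{integer seed (default 1).}
#'     \item{out_dir}{output directory.}
#'   }
#' @return (invisibly) list with the fitted `thresholds`, `detections`,
#'   summary tables, QC results, and the paths written.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  stopifnot(is.list(config))
  mode <- config$mode %||% "ingest"
  if (!mode %in% c("simulate", "ingest"))
    stop("config mode must be 'simulate' or 'ingest'")
  th <- config$thresholds %||% list()
  drop_frac <- th$drop_frac %||% 0.006
  low_frac <- th$low_frac %||% 0.010
  include_controls <- isTRUE(th$include_controls)
  if (drop_frac > low_frac)
    stop("invalid threshold config: low_frac must be >= drop_frac")
  seed <- as.integer(config$seed %||% 1L)
  out_dir <- config$out_dir %||% stop("config needs an out_dir")

  manifest <- config$manifest
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  stopifnot(inherits(manifest, "run_manifest"))

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  on_fail <- function(e) {
    unlink(written)
    stop("pipeline stage failed: ", conditionMessage(e), call. = FALSE)
  }

  tryCatch({
    truth <- NULL
    if (mode == "simulate") {
      params <- do.call(sim_params, config$sim %||% list())
      run <- simulate_run(manifest, params, seed = seed)
      tallies <- run$tallies
      truth <- run$truth
      p <- file.path(out_dir, "tallies.tsv")
      write_tally_table(tallies, p); written <- c(written, p)
      p <- file.path(out_dir, "truth.json")
      jsonlite::write_json(list(occupancy = truth$occupancy,
                                swap_ledger = truth$swap_ledger),
                           p, auto_unbox = TRUE, digits = NA)
      written <- c(written, p)
    } else {
      if (is.null(config$tallies)) stop("ingest mode needs config$tallies")
      tallies <- read_tally_table(config$tallies, manifest)
    }

    res <- classify_run(tallies, manifest, drop_frac = drop_frac,
                        low_frac = low_frac,
                        include_controls = include_controls)
    p <- file.path(out_dir, "detections.csv")
    write_detection_table(res$detections, p); written <- c(written, p)
    p <- file.path(out_dir, "thresholds.json")
    jsonlite::write_json(list(total_reads = res$thresholds$total_reads,
                              cutoff_drop = res$thresholds$cutoff_drop,
                              cutoff_low = res$thresholds$cutoff_low,
                              drop_frac = drop_frac, low_frac = low_frac),
                         p, auto_unbox = TRUE, digits = NA)
    written <- c(written, p)

    qc_neg <- tryCatch(check_negative_controls(res$detections, manifest),
                       warning = function(w) NULL)
    qc_pos <- verify_positive_controls(res$detections, manifest)

    prof <- replicate_profile(res$detections, manifest)
    mat <- site_species_matrix(res$detections, manifest)
    curves <- cumulative_curves(res$detections, manifest)
    p <- file.path(out_dir, "replicate_profile.csv")
    utils::write.csv(prof, p, row.names = FALSE); written <- c(written, p)
    p <- file.path(out_dir, "site_species_matrix.csv")
    utils::write.csv(as.data.frame(mat), p, row.names = TRUE); written <- c(written, p)
    p <- file.path(out_dir, "cumulative_curves.csv")
    utils::write.csv(curves, p, row.names = FALSE); written <- c(written, p)

    actions <- recommend_from_matrix(mat)
    p <- file.path(out_dir, "actions.csv")
    utils::write.csv(actions, p, row.names = FALSE); written <- c(written, p)

    prov <- list(package = "ednadetect",
                 version = as.character(utils::packageVersion("ednadetect")),
                 run_id = manifest$run_id, mode = mode, seed = seed,
                 drop_frac = drop_frac, low_frac = low_frac,
                 include_controls = include_controls,
                 cutoff_drop = res$thresholds$cutoff_drop,
                 cutoff_low = res$thresholds$cutoff_low)
    p <- file.path(out_dir, "provenance.json")
    jsonlite::write_json(prov, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    written <- c(written, p)

    invisible(list(thresholds = res$thresholds, detections = res$detections,
                   truth = truth, replicate_profile = prof,
                   site_species_matrix = mat, cumulative_curves = curves,
                   actions = actions, negative_control_flags = qc_neg,
                   positive_control_report = qc_pos, paths = written))
  }, error = on_fail)
}

#' Action recommendations for every cell of a site x species matrix
#'
#' @param mat result of [site_species_matrix()].
#' @return data.frame with `site_id`, `taxon`, `category`, `actions`
#'   (semicolon-separated).
#' @export
recommend_from_matrix <- function(mat) {
  g <- expand.grid(site_id = rownames(mat), taxon = colnames(mat),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g$category <- mat[cbind(g$site_id, g$taxon)]
  g$actions <- vapply(g$category,
                      function(cc) paste(recommend_action(cc), collapse = ";"),
                      character(1))
  g[order(g$site_id, g$taxon), , drop = FALSE]
}
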