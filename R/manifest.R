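#' Run manifests
#'
#' A run manifest describes the design of one multiplexed sequencing run:
#' the sites sampled (each a river, lake, or reservoir), the ordered
#' biweekly sampling events, the number of replicate water samples taken
#' per site visit, and the control samples placed on each plate.
#'
#' Field sample identifiers are derived deterministically as
#' `<site>_E<event>_R<replicate>` so that a tally table can be re-keyed by
#' site, event, or replicate at will.
#'
#' @param run_id character scalar naming the run.
#' @param sites data.frame with columns `site_id` and `water_body_type`
#'   (one of `"river"`, `"lake"`, `"reservoir"`).
#' @param events data.frame with integer column `event_index` (>= 1,
#'   strictly increasing after sorting) and character column `label`
#'   (e.g. a date). A bare integer count `n` is also accepted and expands
#'   to events `1..n`.
#' @param replicates_per_event integer, number of replicate 500-mL water
#'   samples per site visit (metadata; default 6).
#' @param controls data.frame with columns `sample_id`, `kind`
#'   (`"positive"`/`"negative"`) and, for positive controls, a list-column
#'   `expected_taxa`; or `NULL` for no controls.
#' @return an object of class `run_manifest`.
#' @seealso [read_manifest()], [write_manifest()], [field_samples()]
#' @export
run_manifest <- function(run_id, sites, events, replicates_per_event = 6L,
                         controls = NULL) {
  stopifnot(is.character(run_id), length(run_id) == 1L)
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  if (!all(c("site_id", "water_body_type") %in% names(sites)))
    stop("manifest sites need columns 'site_id' and 'water_body_type'")
  if (anyDuplicated(sites$site_id))
    stop("duplicate site_id in manifest: ",
         paste(unique(sites$site_id[duplicated(sites$site_id)]), collapse = ", "))
  bad <- setdiff(unique(sites$water_body_type), c("river", "lake", "reservoir"))
  if (length(bad))
    stop("unknown water_body_type: ", paste(bad, collapse = ", "))

  if (length(events) == 1L && is.numeric(events))
    events <- data.frame(event_index = seq_len(events),
                         label = sprintf("event_%02d", seq_len(events)))
  events <- as.data.frame(events, stringsAsFactors = FALSE)
  if (!"event_index" %in% names(events))
    stop("manifest events need column 'event_index'")
  if (!"label" %in% names(events))
    events$label <- sprintf("event_%02d", events$event_index)
  events$event_index <- as.integer(events$event_index)
  events <- events[order(events$event_index), , drop = FALSE]
  rownames(events) <- NULL
  if (any(events$event_index < 1L) || anyDuplicated(events$event_index))
    stop("event indices must be >= 1 and strictly increasing")

  replicates_per_event <- as.integer(replicates_per_event)
  stopifnot(replicates_per_event >= 1L)

  if (!is.null(controls)) {
    controls <- as.data.frame(controls, stringsAsFactors = FALSE)
    if (!all(c("sample_id", "kind") %in% names(controls)))
      stop("manifest controls need columns 'sample_id' and 'kind'")
    bad <- setdiff(unique(controls$kind), c("positive", "negative"))
    if (length(bad)) stop("unknown control kind: ", paste(bad, collapse = ", "))
    if (!"expected_taxa" %in% names(controls))
      controls$expected_taxa <- replicate(nrow(controls), character(0), simplify = FALSE)
    if (anyDuplicated(controls$sample_id))
      stop("duplicate control sample_id")
  }

  m <- structure(list(run_id = run_id, sites = sites, events = events,
                      replicates_per_event = replicates_per_event,
                      controls = controls),
                 class = "run_manifest")
  fld <- field_samples(m)$sample_id
  if (!is.null(controls) && any(controls$sample_id %in% fld))
    stop("control sample_id collides with a field sample_id: ",
         paste(intersect(controls$sample_id, fld), collapse = ", "))
  m
}

#' Enumerate the field samples of a manifest
#'
#' @param manifest a [run_manifest()].
#' @return data.frame with one row per field sample: `sample_id`,
#'   `site_id`, `water_body_type`, `event_index`, `replicate`.
#' @export
field_samples <- function(manifest) {
  stopifnot(inherits(manifest, "run_manifest"))
  g <- expand.grid(replicate = seq_len(manifest$replicates_per_event),
                   event_index = manifest$events$event_index,
                   site_id = manifest$sites$site_id,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g <- g[, c("site_id", "event_index", "replicate")]
  g$water_body_type <- manifest$sites$water_body_type[
    match(g$site_id, manifest$sites$site_id)]
  g$sample_id <- sprintf("%s_E%02d_R%d", g$site_id, g$event_index, g$replicate)
  g[, c("sample_id", "site_id", "water_body_type", "event_index", "replicate")]
}

#' All sample ids of a run (field samples plus controls)
#' @param manifest a [run_manifest()].
#' @return character vector.
#' @export
all_sample_ids <- function(manifest) {
  c(field_samples(manifest)$sample_id,
    if (!is.null(manifest$controls)) manifest$controls$sample_id)
}

#' Read a run manifest from JSON
#'
#' Events are sorted by index on load; a control sample id colliding with a
#' derived field sample id, duplicate sites, or out-of-range water-body
#' types are validation errors.
#'
#' @param path path to a manifest JSON file.
#' @return a [run_manifest()].
#' @export
read_manifest <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
  controls <- NULL
  if (!is.null(j$controls) && NROW(j$controls) > 0) {
    controls <- as.data.frame(j$controls, stringsAsFactors = FALSE)
    if (!"expected_taxa" %in% names(controls)) {
      controls$expected_taxa <- replicate(nrow(controls), character(0), simplify = FALSE)
    } else if (!is.list(controls$expected_taxa)) {
      controls$expected_taxa <- as.list(controls$expected_taxa)
    }
    controls$expected_taxa <- lapply(controls$expected_taxa,
                                     function(x) as.character(unlist(x)))
  }
  run_manifest(run_id = j$run_id,
               sites = j$sites,
               events = j$events,
               replicates_per_event = j$replicates_per_event %||% 6L,
               controls = controls)
}

#' Write a run manifest to JSON
#' @param manifest a [run_manifest()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "run_manifest"))
  j <- list(run_id = manifest$run_id,
            sites = manifest$sites,
            events = manifest$events,
            replicates_per_event = manifest$replicates_per_event)
  if (!is.null(manifest$controls)) j$controls <- manifest$controls
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @export
print.run_manifest <- function(x, ...) {
  tab <- table(x$sites$water_body_type)
  cat(sprintf("Run manifest '%s': %d sites (%s), %d events, %d replicates/event",
              x$run_id, nrow(x$sites),
              paste(sprintf("%d %s", tab, names(tab)), collapse = ", "),
              nrow(x$events), x$replicates_per_event))
  if (!is.null(x$controls))
    cat(sprintf(", %d controls", nrow(x$controls)))
  cat("\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
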