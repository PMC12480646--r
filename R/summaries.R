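#' Replicate-level positive detection profile
#'
#' For each (site, event, taxon), counts in how many of the R replicate
#' water samples the taxon was a positive detection — the survey's
#' per-visit detection profile. Only positive categories count (low
#' detections are excluded), and a replicate counts once however many
#' primers detected the taxon in it.
#'
#' @param detections detection data.frame from [classify_run()] (field
#'   samples; control rows are ignored).
#' @param manifest a [run_manifest()]; fixes R and validates replicate
#'   indices.
#' @return data.frame with columns `site_id`, `event_index`, `taxon`,
#'   `k` (replicates with a positive), `R`.
#' @export
replicate_profile <- function(detections, manifest) {
  stopifnot(inherits(manifest, "run_manifest"))
  R <- manifest$replicates_per_event
  d <- field_detections(detections, manifest)
  if (any(d$replicate > R))
    stop("replicate index exceeds the manifest's replicates_per_event")
  d <- d[as.character(d$category) == "positive", , drop = FALSE]
  base <- unique(field_detections(detections, manifest)[
    , c("site_id", "event_index", "taxon"), drop = FALSE])
  if (nrow(d)) {
    u <- unique(d[, c("site_id", "event_index", "taxon", "replicate"),
                  drop = FALSE])
    key <- paste(u$site_id, u$event_index, u$taxon, sep = "\r")
    k <- table(key)
    base$k <- as.integer(k[paste(base$site_id, base$event_index, base$taxon,
                                 sep = "\r")])
    base$k[is.na(base$k)] <- 0L
  } else {
    base$k <- 0L
  }
  base$R <- R
  base <- base[order(base$site_id, base$event_index, base$taxon), , drop = FALSE]
  rownames(base) <- NULL
  base
}

#' Season-aggregated site x species detection matrix
#'
#' One cell per (site, taxon): the best category attained over all events,
#' replicates, and primers (`positive` > `low` > `not_detected`) — the
#' campaign-level detection summary a monitoring table reports.
#'
#' @param detections detection data.frame.
#' @param manifest a [run_manifest()]; all manifest sites appear as rows
#'   even if absent from the table.
#' @return character matrix, sites x taxa, of categories.
#' @export
site_species_matrix <- function(detections, manifest) {
  stopifnot(inherits(manifest, "run_manifest"))
  d <- field_detections(detections, manifest)
  sites <- manifest$sites$site_id
  taxa <- sort(unique(d$taxon))
  mat <- matrix("not_detected", nrow = length(sites), ncol = length(taxa),
                dimnames = list(sites, taxa))
  lvl <- match(as.character(d$category), detection_categories)
  for (i in seq_len(nrow(d))) {
    cur <- match(mat[d$site_id[i], d$taxon[i]], detection_categories)
    if (lvl[i] > cur) mat[d$site_id[i], d$taxon[i]] <- detection_categories[lvl[i]]
  }
  mat
}

#' Cumulative seasonal detection curves
#'
#' For each water-body type (or each site, with `by = "site"`), the
#' cumulative number of distinct taxa with at least one positive detection
#' up to each sampling event, plus the per-event count of distinct
#' positive taxa used for peak-timing analysis. Cumulative curves are
#' non-decreasing by construction and end at the group's total distinct
#' positive taxa.
#'
#' @param detections detection data.frame.
#' @param manifest a [run_manifest()].
#' @param by group curves by `"water_body_type"` (default, pooled across
#'   sites of a type) or `"site"`.
#' @return data.frame with columns `group`, `event_index`,
#'   `n_positive_taxa` (distinct positive taxa at that event),
#'   `new_taxa` (first detected at that event), `cumulative_taxa`.
#' @export
cumulative_curves <- function(detections, manifest, by = c("water_body_type", "site")) {
  stopifnot(inherits(manifest, "run_manifest"))
  by <- match.arg(by)
  d <- field_detections(detections, manifest)
  d$group <- if (by == "site") d$site_id else
    manifest$sites$water_body_type[match(d$site_id, manifest$sites$site_id)]
  groups <- if (by == "site") manifest$sites$site_id else
    unique(manifest$sites$water_body_type)
  events <- manifest$events$event_index

  pos <- d[as.character(d$category) == "positive", , drop = FALSE]
  out <- lapply(groups, function(g) {
    pg <- pos[pos$group == g, , drop = FALSE]
    per_event <- vapply(events, function(e)
      length(unique(pg$taxon[pg$event_index == e])), integer(1))
    first <- if (nrow(pg))
      tapply(pg$event_index, pg$taxon, min) else integer(0)
    new_taxa <- vapply(events, function(e) sum(first == e), integer(1))
    data.frame(group = g, event_index = events,
               n_positive_taxa = per_event, new_taxa = new_taxa,
               cumulative_taxa = cumsum(new_taxa),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Event of peak positive detections
#'
#' The argmax of a per-event positive species count; ties resolve to the
#' earliest event.
#'
#' @param counts numeric vector of per-event counts, in event order (or a
#'   one-group result of [cumulative_curves()], whose `n_positive_taxa`
#'   column is used).
#' @return integer event index (1-based position in `counts`, or the
#'   `event_index` when a curve data.frame is given).
#' @export
peak_event <- function(counts) {
  if (is.data.frame(counts)) {
    stopifnot(all(c("event_index", "n_positive_taxa") %in% names(counts)))
    if (length(unique(counts$group)) > 1L)
      stop("peak_event expects counts for a single group")
    return(counts$event_index[which.max(counts$n_positive_taxa)])
  }
  if (!length(counts)) stop("empty per-event counts")
  which.max(counts)  # first maximum = earliest event on ties
}

# drop control rows and attach nothing; shared guard for summary ops
field_detections <- function(detections, manifest) {
  stopifnot(is.data.frame(detections), "category" %in% names(detections))
  ctl <- if (is.null(manifest$controls)) character(0) else
    manifest$controls$sample_id
  d <- detections[!detections$sample_id %in% ctl, , drop = FALSE]
  if (!all(d$site_id %in% manifest$sites$site_id))
    stop("detection table references site(s) absent from the manifest")
  d
}
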