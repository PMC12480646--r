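#' Read a classified-read tally table
#'
#' A tally table holds one row per (sample, primer, taxon) with the number
#' of demultiplexed, classified reads assigned to that combination — the
#' atomic unit the detection thresholds act on. The expected format is
#' UTF-8 TSV with a header row and columns
#' `sample_id site_id event_index replicate primer_id taxon rank reads`.
#'
#' Duplicate (sample_id, primer_id, taxon) rows are summed on load, so
#' per-lane or per-chunk tallies can be concatenated before reading.
#' Every `sample_id` must resolve to a field sample or a declared control
#' of `manifest`.
#'
#' @param path path to a tab-separated tally file.
#' @param manifest a [run_manifest()] used for sample validation.
#' @return data.frame of validated tallies (one row per sample x primer x
#'   taxon), ordered by sample, primer, taxon.
#' @export
read_tally_table <- function(path, manifest) {
  stopifnot(inherits(manifest, "run_manifest"))
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  validate_tallies(df, manifest)
}

tally_columns <- c("sample_id", "site_id", "event_index", "replicate",
                   "primer_id", "taxon", "rank", "reads")
tally_ranks <- c("species", "genus", "family", "order", "class", "unclassified")

#' Validate and aggregate a tally data.frame
#'
#' Applies the same contract as [read_tally_table()] to an in-memory
#' data.frame: schema check, non-negative integer reads, known sample ids,
#' and aggregation of duplicate (sample, primer, taxon) rows by summing.
#'
#' @param df data.frame with the tally-table columns.
#' @param manifest a [run_manifest()]; pass `NULL` to skip sample-id checks.
#' @return aggregated, ordered tally data.frame.
#' @export
validate_tallies <- function(df, manifest = NULL) {
  missing <- setdiff(tally_columns, names(df))
  if (length(missing))
    stop("tally table is missing column(s): ", paste(missing, collapse = ", "))
  df <- df[, tally_columns, drop = FALSE]
  if (nrow(df) == 0L) return(df)

  if (!is.numeric(df$reads))
    stop("'reads' must be numeric")
  bad <- which(is.na(df$reads) | df$reads < 0 | df$reads != floor(df$reads))
  if (length(bad))
    stop("invalid read count (negative, missing, or non-integer) at row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  df$reads <- as.integer(df$reads)
  df$event_index <- as.integer(df$event_index)
  df$replicate <- as.integer(df$replicate)

  badrank <- setdiff(unique(df$rank), tally_ranks)
  if (length(badrank))
    stop("unknown rank value(s): ", paste(badrank, collapse = ", "))

  if (!is.null(manifest)) {
    known <- all_sample_ids(manifest)
    unknown <- setdiff(unique(df$sample_id), known)
    if (length(unknown))
      stop("sample_id not in manifest (field samples or controls): ",
           paste(utils::head(unknown, 5L), collapse = ", "))
  }

  key <- paste(df$sample_id, df$primer_id, df$taxon, sep = "\r")
  if (anyDuplicated(key)) {
    reads <- rowsum(df$reads, key)
    first <- df[!duplicated(key), , drop = FALSE]
    first$reads <- as.integer(reads[match(paste(first$sample_id, first$primer_id,
                                                first$taxon, sep = "\r"),
                                          rownames(reads)), 1L])
    df <- first
  }
  df <- df[order(df$sample_id, df$primer_id, df$taxon), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write a tally table as TSV
#' @param tallies tally data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tally_table <- function(tallies, path) {
  missing <- setdiff(tally_columns, names(tallies))
  if (length(missing))
    stop("tally table is missing column(s): ", paste(missing, collapse = ", "))
  tallies <- tallies[order(tallies$sample_id, tallies$primer_id, tallies$taxon),
                     tally_columns, drop = FALSE]
  utils::write.table(tallies, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a detection table as CSV
#'
#' The detection table is a tally table augmented with the detection
#' `category` (`not_detected`/`low`/`positive`) and the id of the threshold
#' run that produced it. Output is byte-stable for a fixed input: rows are
#' sorted by site, event, primer, taxon, replicate before writing.
#'
#' @param detections detection data.frame (see [classify_run()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_detection_table <- function(detections, path) {
  if (nrow(detections) == 0L) stop("refusing to write an empty detection table")
  need <- c(tally_columns, "category", "threshold_run_id")
  missing <- setdiff(need, names(detections))
  if (length(missing))
    stop("detection table is missing column(s): ", paste(missing, collapse = ", "))
  detections <- detections[order(detections$site_id, detections$event_index,
                                 detections$primer_id, detections$taxon,
                                 detections$replicate, detections$sample_id),
                           need, drop = FALSE]
  detections$category <- as.character(detections$category)
  utils::write.csv(detections, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a detection table written by [write_detection_table()]
#' @param path CSV path.
#' @return detection data.frame.
#' @export
read_detection_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$category <- factor(df$category, levels = detection_categories)
  df$event_index <- as.integer(df$event_index)
  df$replicate <- as.integer(df$replicate)
  df$reads <- as.integer(df$reads)
  df
}
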