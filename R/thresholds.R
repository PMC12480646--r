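#' Detection categories
#'
#' Every sample x primer x taxon tally is assigned one of three categories:
#' `not_detected` (read sum at or below the drop cutoff — attributed to
#' index swapping or sequencing error and removed), `low` (between the
#' drop cutoff and the low cutoff — a candidate detection requiring
#' validation), or `positive` (above the low cutoff — presumptive species
#' presence).
#' @export
detection_categories <- c("not_detected", "low", "positive")

#' Fit cumulative-tail read-count cutoffs for a sequencing run
#'
#' Multiplexed metabarcoding runs on patterned flow cells present a long
#' tail of low-count tallies produced largely by index (barcode) swapping,
#' which affects roughly 0.2–6% of reads on such platforms. `tail_cutoffs`
#' fits the two per-run cutoffs that mediate this artifact: read sums at or
#' below `cutoff_drop` jointly account for at most `drop_frac` of all
#' classified reads (default 0.6%, the lowest expected single-i7 swap rate)
#' and are dropped; read sums at or below `cutoff_low` account for at most
#' `low_frac` (default 1%) and, when above `cutoff_drop`, are flagged as
#' low detections needing validation.
#'
#' Formally, `cutoff_drop` is the largest read-sum value `v` such that the
#' total reads in tallies `<= v` does not exceed `drop_frac * total`
#' (0 when even the smallest tally busts the budget), and `cutoff_low` is
#' defined analogously with `low_frac`. Cutoffs are values, not row
#' indices, so tallies with equal read sums always share a fate regardless
#' of input order.
#'
#' The appropriate fractions depend on run properties (number of barcodes,
#' read depth, run quality), so both are tunable per dataset.
#'
#' @param reads integer vector of per-combination read sums (the tally
#'   distribution of one run). At least one must be positive.
#' @param drop_frac fraction of total classified reads allowed in the
#'   discarded tail (default 0.006).
#' @param low_frac fraction bounding the low-detection band (default
#'   0.010). Must satisfy `0 <= drop_frac <= low_frac < 1`.
#' @return an object of class `tail_cutoffs`: a list with elements
#'   `total_reads`, `cutoff_drop`, `cutoff_low`, `drop_frac`, `low_frac`,
#'   `n_tallies`, and `value_table` (the per-value cumulative read sums the
#'   fit was derived from).
#' @seealso [predict.tail_cutoffs()] to classify read sums,
#'   [classify_run()] for the full per-run pipeline.
#' @examples
#' ts <- tail_cutoffs(c(1, 2, 3, 14, 80, 300, 9600))
#' ts                      # cutoffs 14 and 80
#' predict(ts, c(0, 14, 80, 81))
#' @export
tail_cutoffs <- function(reads, drop_frac = 0.006, low_frac = 0.010) {
  if (!is.numeric(reads) || length(reads) == 0L)
    stop("'reads' must be a non-empty numeric vector of read sums")
  if (any(is.na(reads) | reads < 0)) stop("read sums must be non-negative")
  if (!is.numeric(drop_frac) || !is.numeric(low_frac) ||
      drop_frac < 0 || drop_frac > low_frac || low_frac >= 1)
    stop("need 0 <= drop_frac <= low_frac < 1")
  reads <- as.numeric(reads)
  total <- sum(reads)
  if (total <= 0) stop("no classified reads: all tallies are zero")

  vals <- sort(unique(reads[reads > 0]))
  cum <- cumsum(vapply(vals, function(v) sum(reads[reads == v]), numeric(1)))

  cutoff_at <- function(frac) {
    budget <- frac * total
    ok <- which(cum <= budget)
    if (length(ok)) vals[max(ok)] else 0
  }

  structure(list(total_reads = total,
                 cutoff_drop = cutoff_at(drop_frac),
                 cutoff_low = cutoff_at(low_frac),
                 drop_frac = drop_frac,
                 low_frac = low_frac,
                 n_tallies = length(reads),
                 value_table = data.frame(value = vals, cum_reads = cum)),
            class = "tail_cutoffs")
}

#' Classify read sums against fitted cutoffs
#'
#' Applies the three-way detection definition: `read_sum <= cutoff_drop`
#' is `not_detected`, `cutoff_drop < read_sum <= cutoff_low` is `low`, and
#' `read_sum > cutoff_low` is `positive`.
#'
#' @param object a fitted [tail_cutoffs()] object.
#' @param newdata numeric vector of read sums to classify.
#' @param ... unused.
#' @return factor with levels `not_detected`, `low`, `positive`.
#' @export
predict.tail_cutoffs <- function(object, newdata, ...) {
  if (any(is.na(newdata) | newdata < 0)) stop("read sums must be non-negative")
  cat <- ifelse(newdata <= object$cutoff_drop, "not_detected",
                ifelse(newdata <= object$cutoff_low, "low", "positive"))
  factor(cat, levels = detection_categories)
}

#' @rdname predict.tail_cutoffs
#' @param read_sum numeric vector of read sums.
#' @param thresholds a fitted [tail_cutoffs()] object.
#' @export
classify_tally <- function(read_sum, thresholds) {
  stopifnot(inherits(thresholds, "tail_cutoffs"))
  predict(thresholds, read_sum)
}

#' @export
print.tail_cutoffs <- function(x, ...) {
  cat(sprintf("Cumulative-tail detection cutoffs (%d tallies, %s reads)\n",
              x$n_tallies, format(x$total_reads, big.mark = ",")))
  cat(sprintf("  drop cutoff: read sums <= %g dropped (budget %.2f%% of reads)\n",
              x$cutoff_drop, 100 * x$drop_frac))
  cat(sprintf("  low  cutoff: read sums in (%g, %g] are low detections (budget %.2f%%)\n",
              x$cutoff_drop, x$cutoff_low, 100 * x$low_frac))
  cat(sprintf("  read sums > %g are positive detections\n", x$cutoff_low))
  invisible(x)
}

#' @export
summary.tail_cutoffs <- function(object, ...) {
  vt <- object$value_table
  dropped <- if (object$cutoff_drop > 0)
    vt$cum_reads[max(which(vt$value <= object$cutoff_drop))] else 0
  lowband <- if (object$cutoff_low > 0)
    vt$cum_reads[max(which(vt$value <= object$cutoff_low))] - dropped else 0
  out <- list(cutoffs = object,
              reads_dropped = dropped,
              reads_low = lowband,
              frac_dropped = dropped / object$total_reads,
              frac_low = lowband / object$total_reads)
  class(out) <- "summary.tail_cutoffs"
  out
}

#' @export
print.summary.tail_cutoffs <- function(x, ...) {
  print(x$cutoffs)
  cat(sprintf("  reads dropped: %g (%.3f%% of total); reads in low band: %g (%.3f%%)\n",
              x$reads_dropped, 100 * x$frac_dropped,
              x$reads_low, 100 * x$frac_low))
  invisible(x)
}

#' Plot the tally distribution with fitted cutoffs
#'
#' Draws the run's read-sum distribution on a log10 x-axis with the drop
#' and low cutoffs marked, the conventional way the long swap tail and the
#' detection bands are visualised.
#'
#' @param x a [tail_cutoffs()] object.
#' @param reads optional raw read sums; defaults to the per-value table
#'   stored in the fit.
#' @param ... passed to [graphics::hist()].
#' @export
plot.tail_cutoffs <- function(x, reads = NULL, ...) {
  if (is.null(reads))
    reads <- rep(x$value_table$value,
                 times = diff(c(0, x$value_table$cum_reads)) / x$value_table$value)
  graphics::hist(log10(reads[reads > 0]),
                 main = "Read-sum distribution with detection cutoffs",
                 xlab = "log10 read sum per sample x primer x taxon", ...)
  if (x$cutoff_drop > 0)
    graphics::abline(v = log10(x$cutoff_drop), col = "red", lty = 2)
  if (x$cutoff_low > 0)
    graphics::abline(v = log10(x$cutoff_low), col = "orange", lty = 2)
  invisible(x)
}

#' Classify every tally of a run
#'
#' The full per-run detection procedure: fit the cumulative-tail cutoffs
#' once from the run's tally distribution, then classify every tally —
#' including control samples — against them. By default control-sample
#' tallies are excluded from the distribution the cutoffs are fitted to,
#' so that deliberately large positive-control counts do not inflate the
#' read total (set `include_controls = TRUE` to keep them in).
#'
#' @param tallies validated tally data.frame (see [read_tally_table()]).
#' @param manifest a [run_manifest()].
#' @param drop_frac,low_frac tail fractions, see [tail_cutoffs()].
#' @param include_controls logical; include control tallies in the
#'   thresholding distribution (default `FALSE`).
#' @return list with elements `thresholds` (a [tail_cutoffs()] object) and
#'   `detections` (the input table plus `category` and `threshold_run_id`
#'   columns; every input tally appears exactly once).
#' @examples
#' m <- run_manifest("toy",
#'                   sites = data.frame(site_id = "S1", water_body_type = "river"),
#'                   events = 1, replicates_per_event = 1)
#' t <- data.frame(sample_id = "S1_E01_R1", site_id = "S1", event_index = 1,
#'                 replicate = 1, primer_id = "P1",
#'                 taxon = paste0("t", 1:7), rank = "species",
#'                 reads = c(1, 2, 3, 14, 80, 300, 9600))
#' r <- classify_run(t, m)
#' table(r$detections$category)   # 4 not_detected, 1 low, 2 positive
#' @export
classify_run <- function(tallies, manifest, drop_frac = 0.006, low_frac = 0.010,
                         include_controls = FALSE) {
  stopifnot(inherits(manifest, "run_manifest"))
  tallies <- validate_tallies(tallies, manifest)
  if (nrow(tallies) == 0L) stop("empty tally table")

  control_ids <- if (is.null(manifest$controls)) character(0) else
    manifest$controls$sample_id
  pool <- if (include_controls) tallies$reads else
    tallies$reads[!tallies$sample_id %in% control_ids]
  if (!length(pool) || sum(pool) <= 0)
    stop("no classified reads available to fit thresholds")

  ts <- tail_cutoffs(pool, drop_frac = drop_frac, low_frac = low_frac)
  detections <- tallies
  detections$category <- predict(ts, detections$reads)
  detections$threshold_run_id <- manifest$run_id
  list(thresholds = ts, detections = detections)
}
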