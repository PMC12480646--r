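#' Monitoring and management actions
#'
#' The action vocabulary of the invasive-species decision framework. A
#' non-detection keeps the taxon in routine multi-species screening; a low
#' detection triggers validation (repeat eDNA sampling plus a traditional
#' survey); a positive or confirmed detection escalates to expanded
#' screening, agency notification, tracking, and containment/eradication
#' planning.
#' @export
management_actions <- c("continue_screening", "resample_edna",
                        "traditional_survey", "expand_screening_sites",
                        "notify_agencies", "add_to_tracking",
                        "containment_and_eradication_planning")

#' Recommend management actions for a detection category
#'
#' @param category one of `not_detected`, `low`, `positive`, or
#'   `confirmed` (a low detection escalated by repetition or survey
#'   confirmation — treated as positive).
#' @param history optional [detection_history()]; when supplied, the
#'   category is first escalated through [escalate()] and actions are
#'   recommended for the effective category.
#' @return character vector of actions (a subset of
#'   [management_actions]), always non-empty.
#' @export
recommend_action <- function(category, history = NULL) {
  if (!is.null(history)) category <- escalate(history)
  category <- as.character(category)
  stopifnot(length(category) == 1L)
  switch(category,
         not_detected = "continue_screening",
         low = c("resample_edna", "traditional_survey"),
         positive = ,
         confirmed = c("expand_screening_sites", "traditional_survey",
                       "notify_agencies", "add_to_tracking",
                       "containment_and_eradication_planning"),
         stop("unknown detection category: ", category))
}

#' Build a detection history for one (site, taxon)
#'
#' @param event integer vector of event indices (strictly increasing).
#' @param category character vector of categories per event.
#' @param confirmed_by_survey logical vector: was the detection confirmed
#'   by a traditional (visual) survey at that event?
#' @param followup_negative single logical: has a dedicated follow-up
#'   campaign (repeat eDNA plus traditional surveys) come back entirely
#'   negative? This is the path by which a lone low detection is resolved
#'   back to "catalogued as not observed".
#' @return an object of class `detection_history`.
#' @export
detection_history <- function(event, category,
                              confirmed_by_survey = rep(FALSE, length(event)),
                              followup_negative = FALSE) {
  stopifnot(length(event) == length(category),
            length(event) == length(confirmed_by_survey))
  event <- as.integer(event)
  if (length(event) && any(diff(event) <= 0))
    stop("history events must be strictly increasing")
  bad <- setdiff(unique(as.character(category)),
                 c(detection_categories, "confirmed"))
  if (length(bad)) stop("unknown category in history: ", paste(bad, collapse = ", "))
  structure(list(event = event, category = as.character(category),
                 confirmed_by_survey = as.logical(confirmed_by_survey),
                 followup_negative = isTRUE(followup_negative)),
            class = "detection_history")
}

#' Escalate a detection history to an effective category
#'
#' Repeated detections or visual confirmation move a taxon from the
#' low-detection tier into the positive/confirmed tier: any positive
#' category, any survey confirmation, or at least `repeat_low` low
#' detections across distinct events yields `positive`. A single
#' unconfirmed low detection remains `low` — unless the history carries a
#' negative follow-up campaign (`followup_negative`), in which case the
#' taxon returns to `not_detected` and routine screening. With no
#' detections at all the result is `not_detected`.
#'
#' Escalation is monotone: adding a detection to a history never
#' downgrades the effective category (the explicit negative-follow-up
#' flag is the one deliberate exception).
#'
#' @param history a [detection_history()].
#' @param repeat_low number of low detections (distinct events) that
#'   counts as "repeated" (default 2).
#' @return one of `not_detected`, `low`, `positive`.
#' @export
escalate <- function(history, repeat_low = 2L) {
  stopifnot(inherits(history, "detection_history"))
  if (!length(history$event)) stop("empty detection history")
  cat <- history$category
  if (any(cat %in% c("positive", "confirmed")) ||
      any(history$confirmed_by_survey))
    return("positive")
  n_low <- sum(cat == "low")
  if (n_low >= repeat_low) return("positive")
  if (n_low >= 1L) {
    if (history$followup_negative) return("not_detected")
    return("low")
  }
  "not_detected"
}

#' Flag contamination in negative controls
#'
#' A clean run shows no low or positive categories in any negative-control
#' sample; anything else is flagged for investigation (it may still be a
#' swap artifact that cleared the cutoffs, but it must be looked at).
#'
#' @param detections detection data.frame from [classify_run()].
#' @param manifest a [run_manifest()] declaring the controls.
#' @return data.frame of flags (`sample_id`, `primer_id`, `taxon`,
#'   `reads`, `category`), empty when the controls are clean. If the
#'   manifest declares no negative controls a warning is raised and an
#'   empty result returned.
#' @export
check_negative_controls <- function(detections, manifest) {
  stopifnot(inherits(manifest, "run_manifest"))
  neg <- if (is.null(manifest$controls)) character(0) else
    manifest$controls$sample_id[manifest$controls$kind == "negative"]
  empty <- data.frame(sample_id = character(0), primer_id = character(0),
                      taxon = character(0), reads = integer(0),
                      category = character(0))
  if (!length(neg)) {
    warning("manifest declares no negative controls")
    return(empty)
  }
  hit <- detections$sample_id %in% neg &
    as.character(detections$category) %in% c("low", "positive")
  if (!any(hit)) return(empty)
  out <- detections[hit, c("sample_id", "primer_id", "taxon", "reads",
                           "category"), drop = FALSE]
  out$category <- as.character(out$category)
  rownames(out) <- NULL
  out
}

#' Verify positive-control recovery
#'
#' For each positive control, compares the taxa expected in the control
#' mix against what the run detected in that sample. A taxon whose best
#' category in the control is `not_detected` (or that is absent entirely)
#' is reported as missing — the signature of a primer failure for that
#' target.
#'
#' @param detections detection data.frame from [classify_run()].
#' @param manifest a [run_manifest()] whose positive controls carry
#'   `expected_taxa`.
#' @return named list (one element per positive control) of lists with
#'   `expected`, `detected`, and `missing` taxon vectors.
#' @export
verify_positive_controls <- function(detections, manifest) {
  stopifnot(inherits(manifest, "run_manifest"))
  ctl <- manifest$controls
  pos <- if (is.null(ctl)) integer(0) else which(ctl$kind == "positive")
  out <- list()
  for (i in pos) {
    expected <- ctl$expected_taxa[[i]]
    if (!length(expected))
      stop("positive control '", ctl$sample_id[i], "' has an empty expected-taxa list")
    d <- detections[detections$sample_id == ctl$sample_id[i] &
                      as.character(detections$category) != "not_detected", ,
                    drop = FALSE]
    detected <- intersect(expected, unique(d$taxon))
    out[[ctl$sample_id[i]]] <- list(expected = expected,
                                    detected = detected,
                                    missing = setdiff(expected, detected))
  }
  out
}
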