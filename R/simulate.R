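#' Simulation parameters for a synthetic multiplexed run
#'
#' Bundles everything the run simulator needs: the taxon panel, which
#' primer amplifies each taxon, the planted site-level occupancy, the
#' per-replicate detection probability, the positive-count model, and the
#' per-read index-swap rate.
#'
#' The count model for a true detection is log-normal, rounded, with a
#' floor of 1 read: heavy-tailed per-taxon read counts are what
#' metabarcoding runs show on a log scale, though no particular
#' distribution is canonical (see the methods vignette). The swap rate is
#' restricted to `[0, 0.06]`, the published range of index-swap fractions
#' for patterned flow cells.
#'
#' @param taxa character vector of taxon names (default 30 synthetic taxa).
#' @param n_primers number of primer sets on the array.
#' @param primer_map named list mapping each taxon to the primer id(s) that
#'   amplify it; default round-robin, one primer per taxon.
#' @param occupancy data.frame with columns `site_id`, `taxon` giving the
#'   planted occupancy, or `NULL` to draw each (site, taxon) pair
#'   independently with probability `occ_prob` inside [simulate_run()].
#' @param occ_prob occupancy probability used when `occupancy` is `NULL`.
#' @param p_detect per-replicate detection probability for an occupied
#'   taxon (default 0.35; field surveys typically recover a species in
#'   one to three of six replicate water samples).
#' @param meanlog,sdlog log-normal parameters of positive read counts
#'   (defaults `log(5000)` and 1).
#' @param swap_rate per-read probability of reassignment to another sample
#'   (default 0.006, the expected single-i7 swap rate; must lie in
#'   `[0, 0.06]`).
#' @param p_control detection probability for positive-control taxa
#'   (default 1).
#' @param availability optional event-indexed availability schedule from
#'   [seasonal_scenario()].
#' @return an object of class `sim_params`.
#' @export
sim_params <- function(taxa = sprintf("Taxon%02d", 1:30),
                       n_primers = 10L,
                       primer_map = NULL,
                       occupancy = NULL,
                       occ_prob = 0.5,
                       p_detect = 0.35,
                       meanlog = log(5000),
                       sdlog = 1,
                       swap_rate = 0.006,
                       p_control = 1,
                       availability = NULL) {
  if (swap_rate < 0 || swap_rate > 0.06)
    stop("swap_rate must lie in [0, 0.06], the published platform range")
  if (p_detect < 0 || p_detect > 1) stop("p_detect must lie in [0, 1]")
  if (occ_prob < 0 || occ_prob > 1) stop("occ_prob must lie in [0, 1]")
  if (p_control < 0 || p_control > 1) stop("p_control must lie in [0, 1]")
  if (sdlog <= 0) stop("sdlog must be positive")
  n_primers <- as.integer(n_primers)
  primers <- sprintf("P%02d", seq_len(n_primers))
  if (is.null(primer_map)) {
    primer_map <- as.list(primers[(seq_along(taxa) - 1L) %% n_primers + 1L])
    names(primer_map) <- taxa
  }
  stopifnot(all(taxa %in% names(primer_map)))
  structure(list(taxa = taxa, primers = primers, primer_map = primer_map,
                 occupancy = occupancy, occ_prob = occ_prob,
                 p_detect = p_detect, meanlog = meanlog, sdlog = sdlog,
                 swap_rate = swap_rate, p_control = p_control,
                 availability = availability),
            class = "sim_params")
}

#' Attach a seasonal availability schedule to simulation parameters
#'
#' Seasonal turnover means different water-body types yield their peak
#' species detections at different times (rivers early in the season,
#' reservoirs mid-season, lakes late). The schedule is a per-event
#' multiplier on the per-replicate detection probability for each
#' water-body type, letting scenarios plant a known peak timing that
#' downstream cumulative-detection summaries should recover.
#'
#' @param manifest a [run_manifest()]; fixes the number of events.
#' @param params a [sim_params()].
#' @param curves named list (names among `river`, `lake`, `reservoir`) of
#'   non-negative numeric vectors of length `nrow(manifest$events)`; each
#'   is a per-event multiplier on `p_detect`. Water-body types without a
#'   curve default to a flat multiplier of 1.
#' @return `params` with the validated schedule attached (an event x type
#'   matrix).
#' @examples
#' m <- example_manifest(n_events = 10)
#' p <- sim_params()
#' p <- seasonal_scenario(m, p, list(river = c(2, 2, 1, rep(0.3, 7)),
#'                                   lake = c(rep(0.3, 7), 1, 2, 2)))
#' @export
seasonal_scenario <- function(manifest, params, curves) {
  stopifnot(inherits(manifest, "run_manifest"), inherits(params, "sim_params"))
  n_events <- nrow(manifest$events)
  types <- c("river", "lake", "reservoir")
  bad <- setdiff(names(curves), types)
  if (length(bad)) stop("unknown water_body_type in curves: ",
                        paste(bad, collapse = ", "))
  sched <- matrix(1, nrow = n_events, ncol = length(types),
                  dimnames = list(NULL, types))
  for (ty in names(curves)) {
    cv <- curves[[ty]]
    if (length(cv) != n_events)
      stop("availability curve for ", ty, " must have one multiplier per event")
    if (any(is.na(cv) | cv < 0))
      stop("availability multipliers must be non-negative")
    sched[, ty] <- cv
  }
  params$availability <- sched
  params
}

#' Simulate one multiplexed metabarcoding run
#'
#' Generates a tally table with known ground truth. For each planted
#' (site, taxon, primer) occupancy and each replicate field sample, a true
#' detection occurs with probability `p_detect` (times the event's
#' availability multiplier, if a seasonal schedule is set); its read count
#' is `max(1, round(rlnorm(meanlog, sdlog)))`. Controls are then added via
#' [add_controls()]. Finally each read is independently reassigned, with
#' probability `swap_rate`, to a uniformly chosen *different* sample in the
#' run — primer and taxon unchanged — modelling single-index (i7) hopping
#' on a shared flow cell. Returned tallies are post-swap sums.
#'
#' All randomness flows from `seed` through one stream with a fixed
#' iteration order (sites, then events, then replicates, in manifest
#' order), so a given (manifest, params, seed) triple always yields a
#' byte-identical table.
#'
#' @param manifest a [run_manifest()].
#' @param params a [sim_params()].
#' @param seed integer seed.
#' @return list with `tallies` (post-swap tally data.frame) and `truth`
#'   (class `true_state`: planted `occupancy`, `pre_swap` counts, and the
#'   `swap_ledger` of (source, destination, primer, taxon, n_reads)
#'   batches). Total reads are conserved: pre-swap and post-swap sums are
#'   always equal.
#' @export
simulate_run <- function(manifest, params, seed = 1L) {
  stopifnot(inherits(manifest, "run_manifest"), inherits(params, "sim_params"))
  set.seed(as.integer(seed))
  fs <- field_samples(manifest)

  occ <- params$occupancy
  if (is.null(occ)) {
    g <- expand.grid(taxon = params$taxa, site_id = manifest$sites$site_id,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    keep <- stats::runif(nrow(g)) < params$occ_prob
    occ <- g[keep, c("site_id", "taxon"), drop = FALSE]
  }
  occ <- as.data.frame(occ, stringsAsFactors = FALSE)
  stopifnot(all(c("site_id", "taxon") %in% names(occ)))
  # expand occupancy to the primers that amplify each taxon
  occ_expanded <- do.call(rbind, lapply(seq_len(nrow(occ)), function(i) {
    data.frame(site_id = occ$site_id[i], taxon = occ$taxon[i],
               primer_id = params$primer_map[[occ$taxon[i]]],
               stringsAsFactors = FALSE)
  }))
  if (is.null(occ_expanded))
    occ_expanded <- data.frame(site_id = character(0), taxon = character(0),
                               primer_id = character(0))

  sched <- params$availability
  rows <- vector("list", nrow(fs))
  for (i in seq_len(nrow(fs))) {
    s <- fs[i, ]
    cand <- occ_expanded[occ_expanded$site_id == s$site_id, , drop = FALSE]
    if (!nrow(cand)) next
    p <- params$p_detect
    if (!is.null(sched)) p <- min(1, p * sched[s$event_index, s$water_body_type])
    hit <- stats::runif(nrow(cand)) < p
    if (!any(hit)) next
    cand <- cand[hit, , drop = FALSE]
    counts <- pmax(1L, as.integer(round(stats::rlnorm(nrow(cand),
                                                      params$meanlog,
                                                      params$sdlog))))
    rows[[i]] <- data.frame(sample_id = s$sample_id, site_id = s$site_id,
                            event_index = s$event_index, replicate = s$replicate,
                            primer_id = cand$primer_id, taxon = cand$taxon,
                            rank = "species", reads = counts,
                            stringsAsFactors = FALSE)
  }
  pre <- do.call(rbind, rows)
  if (is.null(pre))
    pre <- data.frame(sample_id = character(0), site_id = character(0),
                      event_index = integer(0), replicate = integer(0),
                      primer_id = character(0), taxon = character(0),
                      rank = character(0), reads = integer(0))

  pre <- add_controls(pre, manifest, params)

  swapped <- apply_index_swaps(pre, all_sample_ids(manifest), params$swap_rate)

  truth <- structure(list(occupancy = occ_expanded,
                          pre_swap = pre,
                          swap_ledger = swapped$ledger),
                     class = "true_state")
  stopifnot(sum(pre$reads) == sum(swapped$tallies$reads))
  list(tallies = swapped$tallies, truth = truth)
}

#' Add plate controls to a pre-swap tally table
#'
#' Positive controls receive counts drawn from the positive count model for
#' every expected taxon (the extraction mix contains genomic DNA of each
#' control species, 34 by default) on each primer that amplifies it, with
#' per-taxon detection probability `p_control`. Negative controls receive
#' nothing here: any reads they end up with can only arrive through the
#' index-swap mechanism, which is exactly what they are on the plate to
#' monitor. Draws use the current RNG state (call within a seeded context).
#'
#' @param tallies pre-swap field tally data.frame.
#' @param manifest a [run_manifest()] declaring the controls.
#' @param params a [sim_params()].
#' @return the tally table with positive-control rows appended.
#' @export
add_controls <- function(tallies, manifest, params) {
  ctl <- manifest$controls
  if (is.null(ctl)) return(tallies)
  for (i in seq_len(nrow(ctl))) {
    if (ctl$kind[i] != "positive") next
    expected <- ctl$expected_taxa[[i]]
    if (!length(expected))
      stop("positive control '", ctl$sample_id[i], "' has no expected taxa")
    known <- intersect(expected, names(params$primer_map))
    combos <- do.call(rbind, lapply(known, function(tx) {
      data.frame(taxon = tx, primer_id = params$primer_map[[tx]],
                 stringsAsFactors = FALSE)
    }))
    if (is.null(combos)) next
    hit <- stats::runif(nrow(combos)) < params$p_control
    combos <- combos[hit, , drop = FALSE]
    if (!nrow(combos)) next
    counts <- pmax(1L, as.integer(round(stats::rlnorm(nrow(combos),
                                                      params$meanlog,
                                                      params$sdlog))))
    tallies <- rbind(tallies,
                     data.frame(sample_id = ctl$sample_id[i], site_id = "control",
                                event_index = 0L, replicate = 0L,
                                primer_id = combos$primer_id, taxon = combos$taxon,
                                rank = "species", reads = counts,
                                stringsAsFactors = FALSE))
  }
  tallies
}

# Per-read index swapping via binomial thinning: for each source tally draw
# the number of hopped reads Binomial(reads, rate), then scatter them
# uniformly over the other samples of the run (primer and taxon travel with
# the read). Ledger records batches (source, destination, primer, taxon, n).
apply_index_swaps <- function(tallies, sample_ids, rate) {
  empty_ledger <- data.frame(source_sample = character(0),
                             dest_sample = character(0),
                             primer_id = character(0), taxon = character(0),
                             n_reads = integer(0))
  if (rate == 0 || nrow(tallies) == 0L)
    return(list(tallies = finalize_tallies(tallies), ledger = empty_ledger))

  n_swap <- stats::rbinom(nrow(tallies), tallies$reads, rate)
  ledgers <- vector("list", nrow(tallies))
  for (i in which(n_swap > 0L)) {
    dests <- sample_ids[sample_ids != tallies$sample_id[i]]
    d <- sample(dests, n_swap[i], replace = TRUE)
    tab <- table(d)
    ledgers[[i]] <- data.frame(source_sample = tallies$sample_id[i],
                               dest_sample = names(tab),
                               primer_id = tallies$primer_id[i],
                               taxon = tallies$taxon[i],
                               n_reads = as.integer(tab),
                               stringsAsFactors = FALSE)
  }
  ledger <- do.call(rbind, ledgers)
  if (is.null(ledger)) ledger <- empty_ledger

  out <- tallies
  out$reads <- out$reads - n_swap
  if (nrow(ledger)) {
    sample_meta <- sample_metadata_lookup(tallies, sample_ids)
    recv <- data.frame(sample_id = ledger$dest_sample,
                       primer_id = ledger$primer_id,
                       taxon = ledger$taxon,
                       rank = "species",
                       reads = ledger$n_reads,
                       stringsAsFactors = FALSE)
    meta <- sample_meta[match(recv$sample_id, sample_meta$sample_id), ]
    recv$site_id <- meta$site_id
    recv$event_index <- meta$event_index
    recv$replicate <- meta$replicate
    out <- rbind(out, recv[, names(out)])
  }
  list(tallies = finalize_tallies(out), ledger = ledger)
}

# site/event/replicate metadata for every sample id, deriving field-sample
# coordinates from the id pattern and tagging controls
sample_metadata_lookup <- function(tallies, sample_ids) {
  m <- regmatches(sample_ids,
                  regexec("^(.*)_E([0-9]+)_R([0-9]+)$", sample_ids))
  parsed <- t(vapply(m, function(x) {
    if (length(x) == 4L) x[2:4] else c("control", "0", "0")
  }, character(3)))
  data.frame(sample_id = sample_ids,
             site_id = parsed[, 1L],
             event_index = as.integer(parsed[, 2L]),
             replicate = as.integer(parsed[, 3L]),
             stringsAsFactors = FALSE)
}

# aggregate duplicate combos, drop zero rows, fix ordering
finalize_tallies <- function(tallies) {
  tallies <- tallies[tallies$reads > 0L, , drop = FALSE]
  if (!nrow(tallies)) { rownames(tallies) <- NULL; return(tallies) }
  validate_tallies(tallies, manifest = NULL)
}

#' @export
print.true_state <- function(x, ...) {
  cat(sprintf("Simulated ground truth: %d occupied (site, taxon, primer) combos, %d pre-swap tallies (%s reads), %d swap batches (%s reads hopped)\n",
              nrow(x$occupancy), nrow(x$pre_swap),
              format(sum(x$pre_swap$reads), big.mark = ","),
              nrow(x$swap_ledger),
              format(sum(x$swap_ledger$n_reads), big.mark = ",")))
  invisible(x)
}

#' A small example manifest
#'
#' Mirrors the survey design the package targets: three rivers, two lakes
#' and one reservoir sampled biweekly over a season, six replicate 500-mL
#' water samples per visit, and one positive plus one negative control per
#' plate.
#'
#' @param n_events number of biweekly sampling events (default 10).
#' @param replicates replicates per site visit (default 6).
#' @param n_control_taxa number of taxa in the positive-control mix
#'   (default 34).
#' @param taxa taxon names from which the control mix is drawn.
#' @return a [run_manifest()].
#' @export
example_manifest <- function(n_events = 10L, replicates = 6L,
                             n_control_taxa = 34L,
                             taxa = sprintf("Taxon%02d", 1:34)) {
  sites <- data.frame(
    site_id = c("RiverA", "RiverB", "RiverC", "LakeA", "LakeB", "ReservoirA"),
    water_body_type = c("river", "river", "river", "lake", "lake", "reservoir"))
  controls <- data.frame(sample_id = c("Plate1_POS", "Plate1_NEG"),
                         kind = c("positive", "negative"),
                         stringsAsFactors = FALSE)
  controls$expected_taxa <- list(utils::head(taxa, n_control_taxa), character(0))
  run_manifest("example_run", sites, n_events,
               replicates_per_event = replicates, controls = controls)
}
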