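#' Score one simulated run against its ground truth
#'
#' Simulates a run, classifies it, and scores every post-swap tally
#' against the simulator's truth. A combination is *swap-only* if it had
#' no pre-swap reads (every read it holds arrived by index hopping);
#' otherwise it is a *true* (planted) combination. The central operating
#' characteristics are the fraction of swap-only combinations that the
#' thresholds remove or quarantine (specificity against hopping) and the
#' fraction of true combinations retained (sensitivity).
#'
#' @param manifest a [run_manifest()].
#' @param params a [sim_params()].
#' @param drop_frac,low_frac threshold fractions (see [tail_cutoffs()]).
#' @param seed integer seed for the simulated run.
#' @return one-row data.frame: swap-rate and fraction settings; combo
#'   counts by truth class and category (`n_swap_*`, `n_true_*`); and the
#'   derived per-combination rates `swap_fp_rate` (swap-only combos called
#'   positive), `swap_removal_rate` (swap-only combos called not_detected
#'   or low), `true_retention` (true combos surviving the drop cutoff into
#'   low or positive) and `true_positive_rate`. Rates over an empty
#'   denominator are 0.
#' @export
evaluate_once <- function(manifest, params, drop_frac = 0.006,
                          low_frac = 0.010, seed = 1L) {
  run <- simulate_run(manifest, params, seed = seed)
  res <- classify_run(run$tallies, manifest,
                      drop_frac = drop_frac, low_frac = low_frac)
  det <- res$detections

  pre <- run$truth$pre_swap
  pre_key <- paste(pre$sample_id, pre$primer_id, pre$taxon, sep = "\r")
  det_key <- paste(det$sample_id, det$primer_id, det$taxon, sep = "\r")
  is_true <- det_key %in% pre_key
  cat <- as.character(det$category)

  count <- function(truth, category) sum(truth & cat == category)
  n_swap <- sum(!is_true); n_true <- sum(is_true)
  n_swap_removed <- count(!is_true, "not_detected")
  n_swap_low <- count(!is_true, "low")
  n_swap_positive <- count(!is_true, "positive")
  n_true_removed <- count(is_true, "not_detected")
  n_true_low <- count(is_true, "low")
  n_true_positive <- count(is_true, "positive")
  stopifnot(n_swap_removed + n_swap_low + n_swap_positive == n_swap,
            n_true_removed + n_true_low + n_true_positive == n_true,
            n_swap + n_true == nrow(det))

  rate <- function(num, den) if (den > 0) num / den else 0
  data.frame(swap_rate = params$swap_rate, drop_frac = drop_frac,
             low_frac = low_frac, seed = seed,
             n_swap_combos = n_swap, n_swap_removed = n_swap_removed,
             n_swap_low = n_swap_low, n_swap_positive = n_swap_positive,
             n_true_combos = n_true, n_true_removed = n_true_removed,
             n_true_low = n_true_low, n_true_positive = n_true_positive,
             swap_fp_rate = rate(n_swap_positive, n_swap),
             swap_removal_rate = rate(n_swap_removed + n_swap_low, n_swap),
             true_retention = rate(n_true_low + n_true_positive, n_true),
             true_positive_rate = rate(n_true_positive, n_true))
}

#' Sweep swap rates and threshold fractions
#'
#' Runs [evaluate_once()] over the cartesian grid of swap rates and drop
#' fractions, with `n_reps` replicate runs per cell. Seeds are paired
#' across cells (rep i uses `seed + i` everywhere) so that comparisons
#' along the grid — false positives rising with the swap rate, retention
#' falling with the drop fraction — are made on coupled randomness rather
#' than across independent noise.
#'
#' @param manifest a [run_manifest()].
#' @param params a [sim_params()] (its `swap_rate` is overridden by the
#'   grid).
#' @param swap_rates numeric vector of per-read swap rates to test.
#' @param drop_fracs numeric vector of drop fractions to test.
#' @param low_frac the fixed low fraction (default 0.010).
#' @param n_reps replicate runs per grid cell.
#' @param seed base seed.
#' @return data.frame with one row per (swap_rate, drop_frac, rep), the
#'   columns of [evaluate_once()].
#' @export
threshold_sweep <- function(manifest, params, swap_rates = c(0.002, 0.006, 0.013, 0.06),
                            drop_fracs = c(0.002, 0.006, 0.01),
                            low_frac = 0.010, n_reps = 3L, seed = 1L) {
  stopifnot(length(swap_rates) >= 1L, length(drop_fracs) >= 1L, n_reps >= 1L)
  grid <- expand.grid(swap_rate = swap_rates, drop_frac = drop_fracs,
                      rep = seq_len(n_reps), KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    p <- params
    p$swap_rate <- grid$swap_rate[i]
    out <- evaluate_once(manifest, p, drop_frac = grid$drop_frac[i],
                         low_frac = max(low_frac, grid$drop_frac[i]),
                         seed = seed + grid$rep[i])
    out$rep <- grid$rep[i]
    out
  })
  do.call(rbind, rows)
}

#' Summarise a sweep as mean and sd rates per grid cell
#'
#' @param sweep result of [threshold_sweep()].
#' @return data.frame with one row per (swap_rate, drop_frac) and
#'   mean/sd of the four rates.
#' @export
summarise_sweep <- function(sweep) {
  key <- interaction(sweep$swap_rate, sweep$drop_frac, drop = TRUE)
  agg <- function(col, f) as.numeric(tapply(sweep[[col]], key, f))
  cells <- !duplicated(key)
  out <- data.frame(swap_rate = sweep$swap_rate[cells],
                    drop_frac = sweep$drop_frac[cells])
  for (col in c("swap_fp_rate", "swap_removal_rate",
                "true_retention", "true_positive_rate")) {
    out[[paste0(col, "_mean")]] <- agg(col, mean)[match(key[cells], levels(key))]
    out[[paste0(col, "_sd")]] <- agg(col, stats::sd)[match(key[cells], levels(key))]
  }
  out[order(out$swap_rate, out$drop_frac), , drop = FALSE]
}
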