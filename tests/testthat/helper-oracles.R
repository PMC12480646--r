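# Independent oracles and fixture builders shared across the suite.
# Oracles deliberately use naive scans/enumeration, not the package's
# aggregated-cumsum or DP code paths.

# Exhaustive scan: largest candidate value v such that the reads residing in
# tallies <= v stay within frac * total. Candidates are 0 and every distinct
# positive value.
oracle_cutoff <- function(reads, frac) {
  total <- sum(reads)
  best <- 0
  for (v in sort(unique(reads[reads > 0]))) {
    if (sum(reads[reads <= v]) <= frac * total) best <- v
  }
  best
}

oracle_classify <- function(x, cutoff_drop, cutoff_low) {
  ifelse(x <= cutoff_drop, "not_detected",
         ifelse(x <= cutoff_low, "low", "positive"))
}

# Random tally multiset with the long-tail structure of a metabarcoding run:
# many small artifact-scale counts plus a body of large true-scale counts.
random_tally_multiset <- function(n_max = 10000) {
  n <- sample(5:n_max, 1)
  n_small <- ceiling(n * stats::runif(1, 0.3, 0.9))
  small <- stats::rgeom(n_small, 0.35) + 1L
  big <- sample(c(500L, 1200L, 5000L, 9600L, 20000L), n - n_small, replace = TRUE)
  sample(c(small, big))
}

# Brute-force global percent identity by recursive enumeration of all
# alignments: maximise matches, then minimise alignment columns.
brute_identity <- function(q, r) {
  q <- strsplit(q, "")[[1]]; r <- strsplit(r, "")[[1]]
  best <- new.env()
  best$m <- -1L; best$c <- Inf
  rec <- function(i, j, matches, cols) {
    if (i > length(q) && j > length(r)) {
      if (matches > best$m || (matches == best$m && cols < best$c)) {
        best$m <- matches; best$c <- cols
      }
      return(invisible())
    }
    if (i <= length(q) && j <= length(r))
      rec(i + 1L, j + 1L, matches + (q[i] == r[j]), cols + 1L)
    if (i <= length(q)) rec(i + 1L, j, matches, cols + 1L)
    if (j <= length(r)) rec(i, j + 1L, matches, cols + 1L)
  }
  rec(1L, 1L, 0L, 0L)
  100 * best$m / best$c
}

# One 48-field-sample plate (8 sites x 1 event x 6 replicates) with a
# positive and a negative control, matching a single-plate sequencing run.
plate_manifest <- function(taxa = sprintf("Taxon%02d", 1:30)) {
  sites <- data.frame(
    site_id = sprintf("Site%02d", 1:8),
    water_body_type = rep(c("river", "lake", "reservoir"), length.out = 8))
  controls <- data.frame(sample_id = c("P1_POS", "P1_NEG"),
                         kind = c("positive", "negative"),
                         stringsAsFactors = FALSE)
  controls$expected_taxa <- list(taxa, character(0))
  run_manifest("plate1", sites, 1, replicates_per_event = 6,
               controls = controls)
}

# Random detection table over a manifest: random subsets of (sample, primer,
# taxon) combos with random categories, for summary-oracle checks.
random_detection_table <- function(manifest, taxa = sprintf("Taxon%02d", 1:6),
                                   primers = c("P01", "P02")) {
  fs <- field_samples(manifest)
  g <- expand.grid(sample_id = fs$sample_id, primer_id = primers, taxon = taxa,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g <- g[stats::runif(nrow(g)) < 0.4, , drop = FALSE]
  idx <- match(g$sample_id, fs$sample_id)
  g$site_id <- fs$site_id[idx]
  g$event_index <- fs$event_index[idx]
  g$replicate <- fs$replicate[idx]
  g$rank <- "species"
  g$reads <- sample(1:10000, nrow(g), replace = TRUE)
  g$category <- factor(sample(detection_categories, nrow(g), replace = TRUE,
                              prob = c(0.4, 0.2, 0.4)),
                       levels = detection_categories)
  g$threshold_run_id <- manifest$run_id
  rownames(g) <- NULL
  g
}

# Naive group-by recomputations of the three reporting surfaces.
oracle_replicate_profile <- function(det, manifest) {
  det <- det[!det$sample_id %in% manifest$controls$sample_id, , drop = FALSE]
  groups <- unique(det[, c("site_id", "event_index", "taxon")])
  groups <- groups[order(groups$site_id, groups$event_index, groups$taxon), ]
  k <- integer(nrow(groups))
  for (i in seq_len(nrow(groups))) {
    sub <- det[det$site_id == groups$site_id[i] &
                 det$event_index == groups$event_index[i] &
                 det$taxon == groups$taxon[i] &
                 as.character(det$category) == "positive", , drop = FALSE]
    k[i] <- length(unique(sub$replicate))
  }
  groups$k <- k
  rownames(groups) <- NULL
  groups
}

oracle_matrix <- function(det, manifest) {
  det <- det[!det$sample_id %in% manifest$controls$sample_id, , drop = FALSE]
  sites <- manifest$sites$site_id
  taxa <- sort(unique(det$taxon))
  mat <- matrix("not_detected", length(sites), length(taxa),
                dimnames = list(sites, taxa))
  for (s in sites) for (tx in taxa) {
    cats <- as.character(det$category[det$site_id == s & det$taxon == tx])
    if ("positive" %in% cats) mat[s, tx] <- "positive"
    else if ("low" %in% cats) mat[s, tx] <- "low"
  }
  mat
}

oracle_curves <- function(det, manifest) {
  det <- det[!det$sample_id %in% manifest$controls$sample_id, , drop = FALSE]
  det$wbt <- manifest$sites$water_body_type[match(det$site_id,
                                                  manifest$sites$site_id)]
  events <- manifest$events$event_index
  out <- list()
  for (ty in unique(manifest$sites$water_body_type)) {
    pos <- det[det$wbt == ty & as.character(det$category) == "positive", ]
    cum <- integer(length(events)); per <- integer(length(events))
    seen <- character(0)
    for (e in seq_along(events)) {
      now <- unique(pos$taxon[pos$event_index == events[e]])
      per[e] <- length(now)
      seen <- union(seen, now)
      cum[e] <- length(seen)
    }
    out[[ty]] <- data.frame(group = ty, event_index = events,
                            n_positive_taxa = per, cumulative_taxa = cum,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# Shared toy run: the worked 7-tally example
toy_reads <- c(1, 2, 3, 14, 80, 300, 9600)

toy_tally_df <- function() {
  data.frame(sample_id = "RiverA_E01_R1", site_id = "RiverA", event_index = 1L,
             replicate = 1L, primer_id = "P01",
             taxon = sprintf("Taxon%02d", 1:7), rank = "species",
             reads = as.integer(toy_reads), stringsAsFactors = FALSE)
}

toy_manifest <- function() {
  read_manifest(system.file("extdata", "toy_manifest.json",
                            package = "ednadetect"))
}
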