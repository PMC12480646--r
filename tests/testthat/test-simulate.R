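test_that("parameter validation enforces the published ranges", {
  expect_error(sim_params(swap_rate = 0.07), "\\[0, 0.06\\]")
  expect_error(sim_params(swap_rate = -0.01), "\\[0, 0.06\\]")
  expect_error(sim_params(p_detect = 1.5), "\\[0, 1\\]")
  expect_error(sim_params(sdlog = 0), "positive")
})

test_that("with no swapping every nonzero tally lies inside the planted occupancy", {
  m <- plate_manifest()
  p <- sim_params(swap_rate = 0)
  run <- simulate_run(m, p, seed = 11)
  occ_key <- paste(run$truth$occupancy$site_id, run$truth$occupancy$primer_id,
                   run$truth$occupancy$taxon)
  field <- run$tallies[run$tallies$site_id != "control", ]
  expect_true(all(paste(field$site_id, field$primer_id, field$taxon) %in% occ_key))
  expect_equal(nrow(run$truth$swap_ledger), 0L)

  # negative control has zero reads at r = 0
  expect_false("P1_NEG" %in% run$tallies$sample_id)
})

test_that("the same seed reproduces a byte-identical run", {
  m <- plate_manifest()
  p <- sim_params()
  r1 <- simulate_run(m, p, seed = 99)
  r2 <- simulate_run(m, p, seed = 99)
  expect_identical(r1$tallies, r2$tallies)
  expect_identical(r1$truth$swap_ledger, r2$truth$swap_ledger)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_tally_table(r1$tallies, f1); write_tally_table(r2$tallies, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("reads are conserved and the swapped total follows the binomial oracle", {
  m <- plate_manifest()
  p <- sim_params(swap_rate = 0.006)
  for (s in 1:5) {
    run <- simulate_run(m, p, seed = s)
    N <- sum(run$truth$pre_swap$reads)
    expect_equal(sum(run$tallies$reads), N)          # conservation, every seed
    n_swapped <- sum(run$truth$swap_ledger$n_reads)
    expect_lt(abs(n_swapped - 0.006 * N), 4 * sqrt(N * 0.006 * 0.994))
  }
})

test_that("swap bookkeeping is exact: post = pre - outgoing + incoming", {
  m <- plate_manifest()
  p <- sim_params(swap_rate = 0.006)
  run <- simulate_run(m, p, seed = 21)
  pre <- run$truth$pre_swap; led <- run$truth$swap_ledger
  key <- function(s, pr, tx) paste(s, pr, tx, sep = "\r")
  expected <- tapply(pre$reads, key(pre$sample_id, pre$primer_id, pre$taxon), sum)
  out <- tapply(led$n_reads, key(led$source_sample, led$primer_id, led$taxon), sum)
  inc <- tapply(led$n_reads, key(led$dest_sample, led$primer_id, led$taxon), sum)
  all_keys <- unique(c(names(expected), names(inc)))
  get0 <- function(v, k) ifelse(is.na(v[k]), 0, v[k])
  post_expected <- get0(expected, all_keys) - get0(out, all_keys) + get0(inc, all_keys)
  post <- tapply(run$tallies$reads,
                 key(run$tallies$sample_id, run$tallies$primer_id,
                     run$tallies$taxon), sum)
  expect_equal(unname(get0(post, all_keys)), unname(post_expected))

  # every negative-control read traces to a swap-ledger destination
  neg <- run$tallies[run$tallies$sample_id == "P1_NEG", ]
  if (nrow(neg)) {
    inc_neg <- led[led$dest_sample == "P1_NEG", ]
    expect_true(all(paste(neg$primer_id, neg$taxon) %in%
                      paste(inc_neg$primer_id, inc_neg$taxon)))
  }
})

test_that("swap-only tallies sit far below true tallies and carry ~r of the reads", {
  m <- plate_manifest()
  p <- sim_params(swap_rate = 0.006)
  run <- simulate_run(m, p, seed = 31)
  pre_key <- with(run$truth$pre_swap, paste(sample_id, primer_id, taxon))
  tal_key <- with(run$tallies, paste(sample_id, primer_id, taxon))
  swap_only <- run$tallies[!tal_key %in% pre_key, ]
  true_t <- run$tallies[tal_key %in% pre_key, ]
  expect_gt(nrow(swap_only), 0)
  expect_lt(median(swap_only$reads), median(true_t$reads))
  frac <- sum(swap_only$reads) / sum(run$tallies$reads)
  expect_lt(abs(frac - 0.006), 0.003)   # long tail is ~r of the dataset
})

test_that("positive controls recover their expected taxa, negatives stay empty", {
  taxa <- sprintf("Taxon%02d", 1:30)
  m <- plate_manifest(taxa)
  p <- sim_params(taxa = taxa, n_primers = 10, p_control = 1, swap_rate = 0)
  run <- simulate_run(m, p, seed = 8)
  pos <- run$tallies[run$tallies$sample_id == "P1_POS", ]
  # one primer per taxon in the default map: one tally per expected taxon
  expect_equal(sort(unique(pos$taxon)), sort(taxa))
  expect_equal(nrow(pos), length(taxa))
  expect_true(all(pos$reads >= 1))

  ctl <- m$controls
  ctl$expected_taxa[[1]] <- character(0)
  m_bad <- run_manifest("bad", m$sites, nrow(m$events),
                        replicates_per_event = 6, controls = ctl)
  expect_error(simulate_run(m_bad, p, seed = 8), "no expected taxa")
})

test_that("seasonal availability schedules validate and shape detections", {
  m <- example_manifest(n_events = 6)
  p <- sim_params(taxa = sprintf("Taxon%02d", 1:10), n_primers = 5)
  expect_error(seasonal_scenario(m, p, list(river = rep(-1, 6))), "non-negative")
  expect_error(seasonal_scenario(m, p, list(river = rep(1, 5))), "per event")
  expect_error(seasonal_scenario(m, p, list(swamp = rep(1, 6))), "unknown")

  # all-zero curve silences a water body entirely
  p0 <- seasonal_scenario(m, p, list(lake = rep(0, 6)))
  run <- simulate_run(m, p0, seed = 13)
  lakes <- m$sites$site_id[m$sites$water_body_type == "lake"]
  expect_equal(nrow(run$truth$pre_swap[run$truth$pre_swap$site_id %in% lakes, ]), 0L)

  # flat curves leave the run distribution-identical to no schedule
  pf <- seasonal_scenario(m, p, list(river = rep(1, 6), lake = rep(1, 6),
                                     reservoir = rep(1, 6)))
  expect_identical(simulate_run(m, pf, seed = 3)$tallies,
                   simulate_run(m, p, seed = 3)$tallies)
})
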