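test_that("each detection category maps to its management actions", {
  expect_equal(recommend_action("not_detected"), "continue_screening")
  expect_setequal(recommend_action("low"), c("resample_edna", "traditional_survey"))
  full <- c("expand_screening_sites", "traditional_survey", "notify_agencies",
            "add_to_tracking", "containment_and_eradication_planning")
  expect_setequal(recommend_action("positive"), full)
  expect_setequal(recommend_action("confirmed"), full)
  expect_error(recommend_action("maybe"), "unknown")
  # totality: every category yields a non-empty subset of the action vocabulary
  for (cc in c(detection_categories, "confirmed")) {
    a <- recommend_action(cc)
    expect_gt(length(a), 0)
    expect_true(all(a %in% management_actions))
  }
})

test_that("escalation follows the repeated-detection and confirmation rules", {
  # repeated low detections across events escalate
  expect_equal(escalate(detection_history(c(3, 5), c("low", "low"))), "positive")
  # a single unconfirmed low stays low pending validation
  expect_equal(escalate(detection_history(c(3, 5), c("low", "not_detected"))), "low")
  # ... and resolves to not-observed after an all-negative follow-up campaign
  expect_equal(escalate(detection_history(c(3, 5), c("low", "not_detected"),
                                          followup_negative = TRUE)),
               "not_detected")
  # visual/survey confirmation escalates a lone low
  expect_equal(escalate(detection_history(3, "low",
                                          confirmed_by_survey = TRUE)), "positive")
  expect_equal(escalate(detection_history(1, "positive")), "positive")
  expect_equal(escalate(detection_history(1:2, rep("not_detected", 2))),
               "not_detected")
  expect_error(escalate(detection_history(integer(0), character(0))), "empty")
  # configurable repeat count
  expect_equal(escalate(detection_history(c(1, 2), c("low", "low")),
                        repeat_low = 3), "low")
})

test_that("escalation is monotone under added detections", {
  depth <- c(not_detected = 0, low = 1, positive = 2)
  set.seed(23)
  for (i in 1:50) {
    n <- sample(1:5, 1)
    cats <- sample(detection_categories, n, replace = TRUE)
    conf <- stats::runif(n) < 0.2
    h1 <- detection_history(seq_len(n), cats, conf)
    extra_cat <- sample(detection_categories, 1)
    h2 <- detection_history(seq_len(n + 1), c(cats, extra_cat),
                            c(conf, stats::runif(1) < 0.2))
    expect_gte(depth[escalate(h2)], depth[escalate(h1)])
  }
})

test_that("negative-control QC flags exactly the contaminated tallies", {
  m <- toy_manifest()
  det <- classify_run(toy_tally_df(), m)$detections
  expect_equal(nrow(check_negative_controls(det, m)), 0L)

  dirty <- det
  dirty[1, c("sample_id", "site_id")] <- c("Plate1_NEG", "control")
  dirty$category[1] <- "positive"
  flags <- check_negative_controls(dirty, m)
  expect_equal(nrow(flags), 1L)
  expect_equal(flags$sample_id, "Plate1_NEG")
  expect_equal(flags$category, "positive")

  m_noneg <- run_manifest("x", m$sites, 10)
  expect_warning(out <- check_negative_controls(det, m_noneg), "no negative controls")
  expect_equal(nrow(out), 0L)
})

test_that("negative-control flags on a simulated run all trace to the swap ledger", {
  m <- plate_manifest()
  p <- sim_params(swap_rate = 0.006)
  run <- simulate_run(m, p, seed = 17)
  res <- classify_run(run$tallies, m)
  flags <- check_negative_controls(res$detections, m)
  if (nrow(flags)) {
    led <- run$truth$swap_ledger
    dest_key <- paste(led$dest_sample, led$primer_id, led$taxon)
    expect_true(all(paste(flags$sample_id, flags$primer_id, flags$taxon) %in%
                      dest_key))
  }
  succeed()
})

test_that("positive-control verification reports missing expected taxa", {
  taxa <- sprintf("Taxon%02d", 1:30)
  m <- plate_manifest(taxa)
  p <- sim_params(taxa = taxa, n_primers = 10, p_control = 1, swap_rate = 0)
  run <- simulate_run(m, p, seed = 12)
  res <- classify_run(run$tallies, m)
  rep <- verify_positive_controls(res$detections, m)
  expect_named(rep, "P1_POS")
  expect_setequal(rep$P1_POS$expected, taxa)
  # independent recount: missing = expected taxa without a surviving control tally
  ctl_det <- res$detections[res$detections$sample_id == "P1_POS" &
                              res$detections$category != "not_detected", ]
  expect_setequal(rep$P1_POS$missing, setdiff(taxa, ctl_det$taxon))
  expect_setequal(union(rep$P1_POS$detected, rep$P1_POS$missing), taxa)

  # drop one detected taxon from the control sample: it must be reported missing
  victim <- rep$P1_POS$detected[1]
  det2 <- res$detections[!(res$detections$sample_id == "P1_POS" &
                             res$detections$taxon == victim), ]
  rep2 <- verify_positive_controls(det2, m)
  expect_true(victim %in% rep2$P1_POS$missing)

  ctl <- m$controls; ctl$expected_taxa[[1]] <- character(0)
  m_bad <- run_manifest("bad", m$sites, 1, replicates_per_event = 6,
                        controls = ctl)
  expect_error(verify_positive_controls(res$detections, m_bad), "empty expected")
})
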