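test_that("pooling design pools 16 source plates per assay plate", {
  d <- build_pooling_design(1520)
  clones <- d[!is.na(d$clone_id), ]
  expect_equal(unique(clones$assay_plate), "AP001")
  per_well <- dplyr::count(clones, assay_well)
  expect_equal(nrow(per_well), 95)
  expect_true(all(per_well$n == 16))
  # clones map to exactly one assay well each
  expect_equal(nrow(clones), 1520)
  expect_false(any(duplicated(clones$clone_id)))
  # control wells carry no clone
  expect_true(all(is.na(d$clone_id[d$assay_well == "H12"])))
})

test_that("a pool factor of 1 is the identity mapping", {
  d <- build_pooling_design(95, plates_per_pool = 1)
  clones <- d[!is.na(d$clone_id), ]
  expect_equal(clones$assay_well, clones$source_well)
  expect_equal(nrow(dplyr::distinct(clones, assay_plate)), 1)
})

test_that("a day of screening at the default design spans 8 assay plates", {
  d <- build_pooling_design(12160)
  expect_equal(length(unique(d$assay_plate)), 8)
})

test_that("ragged final pools simply hold fewer clones", {
  d <- build_pooling_design(1520 + 80)
  clones <- d[!is.na(d$clone_id), ]
  depth <- dplyr::count(clones, assay_plate, assay_well)
  expect_true(all(depth$n[depth$assay_plate == "AP001"] == 16))
  expect_true(all(depth$n[depth$assay_plate == "AP002"] == 1))
})

test_that("thresholds are the plate mean plus two standard deviations", {
  # 95 wells at 10.0 and one outlier at 1000.0; expected statistics are
  # recomputed here by direct summation as an independent oracle
  values <- c(rep(10, 95), 1000)
  r <- plate_readings(values)
  mu <- sum(values) / 96
  sd_p <- sqrt(sum((values - mu)^2) / 96)
  sd_s <- sqrt(sum((values - mu)^2) / 95)

  pop <- hit_thresholds(call_hits(r))
  expect_equal(pop$mean, 20.3125)
  expect_equal(pop$sd, sd_p, tolerance = 1e-12)
  expect_equal(pop$threshold, mu + 2 * sd_p, tolerance = 1e-12)

  smp <- hit_thresholds(call_hits(r, sd_type = "sample"))
  expect_equal(smp$sd, sd_s, tolerance = 1e-12)
  expect_equal(smp$sd, 101.0415, tolerance = 1e-4)
  expect_equal(smp$threshold, 222.3954, tolerance = 1e-3)

  for (h in list(call_hits(r), call_hits(r, sd_type = "sample"))) {
    expect_equal(sum(h$positive), 1)
    expect_true(h$positive[h$well == well_labels()[96]])
  }
})

test_that("identical wells produce zero positives under the strict rule", {
  h <- call_hits(plate_readings(rep(7, 96)))
  expect_equal(sum(h$positive), 0)
  # non-strict inequality flips every well positive (value == threshold)
  h2 <- call_hits(plate_readings(rep(7, 96)), strict = FALSE)
  expect_equal(sum(h2$positive), 96)
})

test_that("hit calling is invariant to well order and monotone in the multiplier", {
  withr::with_seed(8, {
    r <- plate_readings(rnorm(96, 10, 1))
  })
  h1 <- call_hits(r)
  shuffled <- r[sample(nrow(r)), ]
  h2 <- call_hits(shuffled)
  expect_equal(dplyr::arrange(tibble::as_tibble(h1), well),
               dplyr::arrange(tibble::as_tibble(h2), well))
  pos2 <- h1$well[h1$positive]
  pos3 <- {
    h <- call_hits(r, sd_multiplier = 3)
    h$well[h$positive]
  }
  expect_true(all(pos3 %in% pos2))
})

test_that("a well positive at either timepoint is positive under rule 'any'", {
  r <- dplyr::bind_rows(
    plate_readings(c(20, rep(10, 95)), timepoint = "24h"),
    plate_readings(rep(10, 96), timepoint = "5d"))
  expect_equal(sum(call_hits(r)$positive), 1)
  expect_equal(sum(call_hits(r, combine_timepoints = "all")$positive), 0)
  expect_equal(sum(call_hits(r, combine_timepoints = "5d")$positive), 0)
})

test_that("visual readings bypass thresholds; bad input is rejected", {
  r <- plate_readings(c(1, 0, 0, 1, rep(0, 92)), modality = "visual")
  h <- call_hits(r)
  expect_equal(sum(h$positive), 2)
  expect_true(all(is.na(hit_thresholds(h)$threshold)))

  expect_error(call_hits(plate_readings(c(1, NA, rep(1, 94)))),
               class = "screenbin_data_error")
  expect_error(call_hits(plate_readings(10)[1, ]),
               class = "screenbin_insufficient_data")
  expect_error(call_hits(plate_readings(rep(1, 96)), sd_multiplier = 0),
               class = "screenbin_invalid_parameter")
})

test_that("deconvolution expands every clone of a positive pooled well", {
  design <- build_pooling_design(1520)
  hits <- tibble::tibble(plate_id = "AP001", well = c("A1", "B2"),
                         substrate = c("s1", "s1"),
                         positive = c(TRUE, FALSE))
  cand <- deconvolve(hits, design)
  expect_equal(nrow(cand), 16)
  expect_equal(unique(cand$assay_well), "A1")

  # no positives -> empty candidate list
  none <- deconvolve(dplyr::mutate(hits, positive = FALSE), design)
  expect_equal(nrow(none), 0)

  # one well firing on two substrates tags all 16 clones with both
  two <- deconvolve(tibble::tibble(plate_id = "AP001", well = "A1",
                                   substrate = c("s1", "s2"),
                                   positive = TRUE), design)
  expect_equal(nrow(two), 32)
  expect_true(all(table(two$clone_id) == 2))

  expect_error(
    deconvolve(tibble::tibble(plate_id = "AP999", well = "A1",
                              substrate = "s1", positive = TRUE), design),
    class = "screenbin_consistency_error")
})

test_that("confirmation recovers a planted active clone and nothing else", {
  lib <- small_library(n_clones = 20, seed = 81, sequences = FALSE)
  # one clone active on two substrates, signal 10 background-sd above mean
  lib <- set_true_activities(lib, rep("clone_00007", 2),
                             c("4-MUB-beta-D-cellobiose",
                               "4-MUB-beta-D-xyloside"))
  design <- build_expansion_design(lib$clones$clone_id)
  noise <- noise_model(background_mean = 10, background_sd = 1,
                       active_signal_mean = 10, active_signal_sd = 0)
  r <- simulate_readings(lib, design, noise, seed = 5)
  prof <- confirm_clones(r, design)
  found <- dplyr::filter(tibble::as_tibble(prof),
                         clone_id == "clone_00007")
  expect_setequal(found$substrate, c("4-MUB-beta-D-cellobiose",
                                     "4-MUB-beta-D-xyloside"))
  expect_setequal(profile_clones(prof), lib$clones$clone_id)

  # an all-background expansion plate confirms nothing
  quiet <- simulate_readings(small_library(20, seed = 81,
                                           sequences = FALSE),
                             design, exact_noise(), seed = 5)
  expect_equal(nrow(confirm_clones(quiet, design)), 0)

  # pooled wells are rejected
  pooled <- build_pooling_design(40, clone_ids = sprintf("c%02d", 1:40),
                                 plates_per_pool = 2, clones_per_plate = 20)
  expect_error(confirm_clones(r, pooled),
               class = "screenbin_invalid_parameter")
})

test_that("near-threshold positives require reproduction in a re-screen", {
  clones <- sprintf("c%02d", 1:95)
  design <- build_expansion_design(clones)
  base <- rep(10, 96)
  # delta = 1: clears the 2SD threshold by < 10% of it (borderline);
  # delta = 5 on a second substrate: a confident positive
  border <- base; border[1] <- 11
  confident <- base; confident[1] <- 15
  r <- dplyr::bind_rows(plate_readings(border, plate_id = "EP001",
                                       substrate = "s1"),
                        plate_readings(confident, plate_id = "EP001",
                                       substrate = "s2"))
  flat <- dplyr::bind_rows(plate_readings(base, plate_id = "EP001",
                                          substrate = "s1"),
                           plate_readings(base, plate_id = "EP001",
                                          substrate = "s2"))

  no_rescreen <- confirm_clones(r, design)
  expect_setequal(no_rescreen$substrate, c("s1", "s2"))
  expect_true(no_rescreen$near_threshold[no_rescreen$substrate == "s1"])
  expect_false(no_rescreen$near_threshold[no_rescreen$substrate == "s2"])

  # borderline hit vanishes when the re-screen is flat ...
  adjudicated <- confirm_clones(r, design, rescreen_readings = flat)
  expect_equal(adjudicated$substrate, "s2")
  # ... and survives when it reproduces
  kept <- confirm_clones(r, design, rescreen_readings = r)
  expect_setequal(kept$substrate, c("s1", "s2"))
})

test_that("limit of detection is the lowest concentration above background", {
  s <- tibble::tibble(concentration = c(0.001, 0.01, 0.1),
                      value = c(4.9, 5.1, 9.0))
  expect_equal(determine_lod(s, background = 5.0), 0.01)
  expect_true(is.na(determine_lod(s, background = 10)))
  expect_equal(determine_lod(s[3, ], background = 5), 0.1)
  expect_error(determine_lod(s[0, ], background = 5),
               class = "screenbin_invalid_parameter")
  expect_error(determine_lod(s[c(3, 1, 2), ], background = 5),
               class = "screenbin_invalid_parameter")
})

test_that("screen tallies aggregate profiles correctly", {
  panel <- substrate_panel()
  prof <- activity_profile(
    tibble::tibble(clone_id = c("A", "A", "B"),
                   substrate = panel$substrate[c(1, 2, 1)]),
    clones = c("A", "B", "C"))
  s <- tally_screen(prof, n_clones_screened = 3)
  expect_equal(s$n_positive_assays, 3)
  expect_equal(s$n_unique_positive_clones, 2)
  expect_equal(s$n_multi_substrate_clones, 1)
  expect_equal(s$n_assays, 3 * 14)
  expect_equal(s$per_substrate$n_positive[1], 2)
  expect_equal(s$per_substrate$frequency_pct[1], 100 * 2 / 3)

  empty <- tally_screen(activity_profile(
    tibble::tibble(clone_id = character(), substrate = character()),
    clones = character()), n_clones_screened = 10)
  expect_equal(empty$n_positive_assays, 0)
  expect_equal(empty$avg_positive_rate_pct, 0)

  expect_error(tally_screen(prof, n_clones_screened = 1),
               class = "screenbin_consistency_error")
  bad <- activity_profile(tibble::tibble(clone_id = "A", substrate = "nope"),
                          clones = "A")
  expect_error(tally_screen(bad, 5), class = "screenbin_consistency_error")
})

test_that("every confirmed clone traces back to a positive pooled well", {
  lib <- small_library(n_clones = 95, seed = 91, active_gene_rate = 0.3,
                       sequences = FALSE)
  design <- build_pooling_design(95, clone_ids = lib$clones$clone_id)
  pooled <- simulate_readings(lib, design, seed = 6)
  hits <- call_hits(pooled)
  cand <- deconvolve(hits, design)
  if (nrow(cand) > 0) {
    ed <- build_expansion_design(cand$clone_id)
    prof <- confirm_clones(simulate_readings(lib, ed, seed = 7), ed)
    confirmed <- dplyr::semi_join(tibble::as_tibble(prof), cand,
                                  by = c("clone_id", "substrate"))
    expect_true(all(confirmed$clone_id %in% cand$clone_id))
    # internal consistency: uniques cannot exceed positive pairs
    tl <- tally_screen(
      activity_profile(confirmed, clones = lib$clones$clone_id), 95)
    expect_lte(tl$n_unique_positive_clones, tl$n_positive_assays)
  } else {
    succeed("no positive wells at this seed")
  }
})
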