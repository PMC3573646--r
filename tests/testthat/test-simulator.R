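# DDA simulator: scan-event arithmetic, determinism, threshold semantics,
# artifact channel and ground-truth round trips.

test_that("scan-event arithmetic matches the acquisition method design", {
  expect_identical(count_scan_events(acquisition_scheme()), 107L)
  expect_identical(count_scan_events(acquisition_scheme(max_level = 2)), 2L)
  expect_identical(
    count_scan_events(acquisition_scheme(c("2" = 1L, "3" = 1L, "4" = 1L))), 5L)
})

test_that("the packaged glutathione fixture matches its published shape", {
  fx <- glutathione_fixture()
  expect_length(fx$efp, 21)
  expect_identical(fx$efp[1], "C10H18N3O6S1")
  expect_identical(serialize_formula(fx$truth$root$formula, "efp_token"),
                   "C10H18N3O6S1")
  expect_identical(
    fx$table$efp[fx$table$display == "C6H6NS"],
    "C10H18N3O6S1||C8H13N2O4S1||C7H11N2O2S1||C7H8N1O2S1||C6H6N1S1")
  expect_setequal(truth_efps(fx$truth), fx$efp)
  # printed (measured) masses = theoretical ion m/z shifted by the printed
  # ppm error, to within one unit in the last printed digit (rounding
  # boundaries in the 3-decimal table)
  theo <- vapply(strsplit(fx$table$efp, "||", fixed = TRUE),
                 function(p) ion_mz(p[length(p)], 1L), numeric(1))
  observed <- theo * (1 + fx$table$ppm_error * 1e-6)
  expect_true(all(abs(observed - fx$table$printed_mz) < 1e-3))
})

test_that("simulation is deterministic under a fixed seed", {
  fx <- glutathione_fixture()
  s1 <- simulate_acquisition(fx$truth, noise = noise_model(2, 0.2, 1, seed = 42),
                             repetitions = 3)
  s2 <- simulate_acquisition(fx$truth, noise = noise_model(2, 0.2, 1, seed = 42),
                             repetitions = 3)
  expect_identical(s1, s2)
  s3 <- simulate_acquisition(fx$truth, noise = noise_model(2, 0.2, 1, seed = 43),
                             repetitions = 3)
  expect_false(identical(s1, s3))
})

test_that("a precursor below the intensity threshold is not fragmented", {
  fx <- glutathione_fixture()
  scans <- simulate_acquisition(fx$truth, noise = noise_model(seed = 1),
                                root_intensity = 1000)
  expect_length(scans, 1)
  expect_identical(scans[[1]]$ms_level, 1L)
})

test_that("truth deeper than the scheme's max level is refused", {
  fx <- glutathione_fixture()
  expect_error(
    simulate_acquisition(fx$truth, acquisition_scheme(max_level = 3)),
    "deeper")
})

test_that("zero-noise round trips recover random ground truths exactly", {
  withr::with_seed(31, {
    for (i in 1:10) {
      truth <- random_truth_tree(n_nodes = sample(6:14, 1))
      scans <- simulate_acquisition(truth, noise = noise_model(seed = i))
      ft <- assign_tree(link_precursors(scans)[[1]])
      expect_setequal(efp_strings(ft), truth_efps(truth))
    }
  })
})

test_that("file-based round trip through mzXML preserves the EFP set", {
  withr::with_seed(17, {
    truth <- random_truth_tree(n_nodes = 10)
    scans <- simulate_acquisition(truth, noise = noise_model(seed = 99))
    path <- withr::local_tempfile(fileext = ".mzXML")
    write_mzxml(scans, path)
    ft <- assign_tree(link_precursors(read_mzxml(path))[[1]])
    expect_setequal(efp_strings(ft), truth_efps(truth))
  })
})

test_that("artifact peaks admit no formula and never reach the tree", {
  fx <- glutathione_fixture()
  for (seed in 1:6) {
    scans <- simulate_acquisition(fx$truth,
                                  noise = noise_model(artifact_rate = 3, seed = seed))
    n_peaks <- sum(vapply(scans, function(s) nrow(s$peaks), integer(1)))
    expect_gt(n_peaks, 21)  # artifacts were injected
    ft <- assign_tree(link_precursors(scans)[[1]])
    expect_setequal(efp_strings(ft), fx$efp)
    expect_match(ft$log, "no formula under cap", all = FALSE)
  }
})

test_that("mass noise at the reported error scale keeps recovery near-total", {
  fx <- glutathione_fixture()
  recovered <- vapply(1:10, function(seed) {
    scans <- simulate_acquisition(fx$truth,
                                  noise = noise_model(mass_sigma_ppm = 2, seed = seed))
    ft <- assign_tree(link_precursors(scans)[[1]], "C10H18N3O6S")
    length(intersect(efp_strings(ft), fx$efp)) / length(fx$efp)
  }, numeric(1))
  expect_gte(mean(recovered), 0.95)
})

test_that("isomer fixture validates its feasibility preconditions", {
  expect_error(make_isomer_pair_fixture(5, 5, 0), "root path")
  expect_error(make_isomer_pair_fixture(5, 5, 6), "exceed")
  fix <- make_isomer_pair_fixture(7, 7, 7, seed = 4)
  expect_setequal(fix$efp_a, fix$efp_b)
  expect_equal(tanimoto(fix$efp_a, fix$efp_b), 1)
  # trees respect the sub-formula invariant by construction
  expect_s3_class(fix$truth_a, "truth_tree")
  expect_s3_class(fix$truth_b, "truth_tree")
})

test_that("truth_from_paths rejects hierarchy-violating paths", {
  expect_error(truth_from_paths(c("C2H4O1", "C2H4O1||C3H6O1")), "sub-formula")
  expect_error(truth_from_paths(c("C2H4O1", "C3H6O1")), "one root")
})
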