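# mzXML reading, precursor linking, normalization, composite spectra and
# the peak-tree JSON round trip.

test_that("a minimal hand-written mzXML file is read correctly", {
  scans <- list(
    scan("1", 1, data.frame(mz = 308.0909, intensity = 1e6)),
    scan("2", 2, data.frame(mz = c(179.0487, 162.0222, 233.0594),
                            intensity = c(2e5, 6.6e4, 5e4)),
         precursor_mz = 308.0909, precursor_scan_id = "1")
  )
  path <- withr::local_tempfile(fileext = ".mzXML")
  write_minimal_mzxml(path, scans)
  got <- read_mzxml(path)
  expect_length(got, 2)
  expect_identical(got[[2]]$ms_level, 2L)
  expect_equal(got[[2]]$precursor_mz, 308.0909, tolerance = 1e-5)
  expect_identical(got[[2]]$precursor_scan_id, "1")
  expect_equal(got[[2]]$peaks$mz, c(179.0487, 162.0222, 233.0594),
               tolerance = 1e-7)
})

test_that("reading a simulator-written file recovers m/z and intensities", {
  fx <- glutathione_fixture()
  scans <- simulate_acquisition(fx$truth, noise = noise_model(seed = 2))
  path <- withr::local_tempfile(fileext = ".mzXML")
  write_mzxml(scans, path)
  got <- read_mzxml(path)
  expect_length(got, length(scans))
  for (i in seq_along(scans)) {
    want <- scans[[i]]$peaks[order(scans[[i]]$peaks$mz), ]
    expect_equal(got[[i]]$peaks$mz, want$mz, tolerance = 1e-4)
    expect_equal(got[[i]]$peaks$intensity, want$intensity)
  }
})

test_that("missing files error cleanly", {
  expect_error(read_mzxml("does-not-exist.mzXML"), "no such file")
})

test_that("scan construction enforces level/precursor consistency", {
  expect_error(scan("1", 1, data.frame(mz = 100, intensity = 1),
                    precursor_mz = 50), "MS1")
  expect_error(scan("2", 2, data.frame(mz = 100, intensity = 1)), "require")
  expect_error(scan("1", 1, data.frame(mz = -5, intensity = 1)), "mz > 0")
})

test_that("linking splits repetitions and drops orphans with a warning", {
  fx <- glutathione_fixture()
  scans <- simulate_acquisition(fx$truth, noise = noise_model(seed = 4),
                                repetitions = 5)
  trees <- link_precursors(scans)
  expect_length(trees, 5)
  expect_identical(vapply(trees, function(t) t$repetition, integer(1)), 1:5)
  for (tr in trees) expect_silent(validate_spectrum_tree(tr))

  orphan <- scan("99", 2, data.frame(mz = 100, intensity = 10),
                 precursor_mz = 555.5)
  expect_warning(trees2 <- link_precursors(c(scans[1:2], list(orphan))),
                 "orphan")
  expect_false("99" %in% names(trees2[[1]]$scans))
})

test_that("a saturating truth tree emits exactly the scheme's scan count", {
  # wide 3-level tree: root with 5 children, each with enough grandchildren
  root <- "C16H23N2O6S1"
  l2 <- paste0(root, "||", c("C15H21N2O5S1", "C14H19N2O4S1", "C13H17N2O3S1",
                             "C14H21N2O5S1", "C15H19N2O4S1"))
  scheme <- acquisition_scheme(c("2" = 3L), max_level = 3L)
  truth <- truth_from_paths(c(root, l2, paste0(l2[1:3], "||C12H15N2O2S1")),
                            c(100, 100, 90, 80, 70, 60, 100, 100, 100))
  scans <- simulate_acquisition(truth, scheme, noise_model(seed = 1))
  expect_length(scans, count_scan_events(scheme))
})

test_that("normalization is idempotent and rejects all-zero scans", {
  s <- scan("1", 1, data.frame(mz = c(100, 200, 300), intensity = c(3, 6, 1.5)))
  n1 <- normalize_intensities(s)
  expect_equal(n1$peaks$rel_intensity, c(50, 100, 25))
  expect_identical(normalize_intensities(n1)$peaks, n1$peaks)
  z <- scan("1", 1, data.frame(mz = 100, intensity = 0))
  expect_error(normalize_intensities(z), "positive intensity")
})

test_that("threshold filter removes sub-threshold and low-SNR peaks", {
  s <- scan("1", 1, data.frame(mz = c(100, 200, 300),
                               intensity = c(10, 5000, 9000)))
  expect_equal(nrow(threshold_filter(s, min_intensity = 4500)$peaks), 2)
  expect_identical(threshold_filter(s)$peaks, s$peaks)
  expect_equal(nrow(threshold_filter(s, min_snr = 1.5)$peaks), 1)
  empty <- scan("1", 1, data.frame(mz = numeric(), intensity = numeric()))
  expect_equal(nrow(threshold_filter(empty, 100)$peaks), 0)
})

test_that("composite spectrum merges within tolerance, order-invariantly", {
  s1 <- scan("1", 1, data.frame(mz = 308.0909, intensity = 100))
  s2 <- scan("2", 2, data.frame(mz = c(179.049, 116.016), intensity = c(80, 10)),
             precursor_mz = 308.0909, precursor_scan_id = "1")
  s3 <- scan("3", 3, data.frame(mz = c(116.0161, 88.021), intensity = c(40, 5)),
             precursor_mz = 179.049, precursor_scan_id = "2")
  tree <- link_precursors(list(s1, s2, s3))[[1]]
  comp <- composite_spectrum(tree, bin_tol_mz = 0.01)
  expect_equal(nrow(comp), 4)  # 116.016 peaks coalesced
  merged <- comp[abs(comp$mz - 116.016) < 0.01, ]
  expect_equal(merged$intensity, 50)
  expect_equal(max(comp$rel_intensity), 100)

  tree_perm <- tree
  tree_perm$scans <- rev(tree_perm$scans)
  expect_equal(composite_spectrum(tree_perm, 0.01), comp)
})

test_that("peak-tree JSON round trips losslessly and rejects bad links", {
  fx <- glutathione_fixture()
  scans <- simulate_acquisition(fx$truth, noise = noise_model(seed = 6),
                                repetitions = 2)
  trees <- link_precursors(scans)
  path <- withr::local_tempfile(fileext = ".json")
  write_peaktree_json(trees, path)
  back <- read_peaktree_json(path)
  expect_length(back, length(trees))
  for (i in seq_along(trees)) {
    expect_identical(names(back[[i]]$scans), names(trees[[i]]$scans))
    expect_identical(back[[i]]$parent, trees[[i]]$parent)
    for (id in names(trees[[i]]$scans)) {
      expect_equal(back[[i]]$scans[[id]]$peaks$mz, trees[[i]]$scans[[id]]$peaks$mz)
      expect_equal(back[[i]]$scans[[id]]$peaks$intensity,
                   trees[[i]]$scans[[id]]$peaks$intensity)
    }
  }
  # level-inconsistent (cycle-like) link structure is rejected
  bad <- '{"run":{"polarity":1,"trees":[{"repetition":1,"scans":[
    {"id":"1","level":1,"peaks":[[100,10]]},
    {"id":"2","level":2,"precursor_mz":100,"precursor_id":"3","peaks":[[90,5]]},
    {"id":"3","level":2,"precursor_mz":90,"precursor_id":"2","peaks":[[100,5]]}
  ]}]}}'
  bad_path <- withr::local_tempfile(fileext = ".json")
  writeLines(bad, bad_path)
  expect_error(read_peaktree_json(bad_path), "level|cyclic")
})

test_that("empty tree list writes a valid document", {
  path <- withr::local_tempfile(fileext = ".json")
  write_peaktree_json(list(), path)
  expect_length(read_peaktree_json(path), 0)
})
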