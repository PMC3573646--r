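# Hierarchy-constrained formula assignment, artifact removal, consensus
# aggregation and tree exports.

glut_tree <- function(seed = 1, ...) {
  fx <- glutathione_fixture()
  scans <- simulate_acquisition(fx$truth, noise = noise_model(seed = seed, ...))
  link_precursors(scans)[[1]]
}

test_that("root assignment validates known formulas and enumerates unknowns", {
  tree <- glut_tree()
  known <- assign_root(tree, "C10H18N3O6S")
  expect_identical(known$token, "C10H18N3O6S1")
  expect_equal(known$ppm_error, -0.5, tolerance = 1e-3)
  free <- assign_root(tree)
  expect_identical(free$token, "C10H18N3O6S1")
  bad <- tree
  bad$root_mz <- 308.2
  expect_error(assign_root(bad, "C10H18N3O6S"), "unassignable")
})

test_that("the full pipeline reproduces the 21 reported glutathione EFPs", {
  fx <- glutathione_fixture()
  ft <- assign_tree(glut_tree())
  expect_setequal(efp_strings(ft), fx$efp)
  expect_equal(nrow(ft$nodes), 21)
  expect_false(any(ft$nodes$ambiguous))
  # recovered mass errors agree with the reported per-path values
  m <- merge(ft$nodes[c("efp", "ppm_error")],
             fx$table[c("efp", "ppm_error")], by = "efp")
  expect_equal(m$ppm_error.x, m$ppm_error.y, tolerance = 1e-4)
  # and relative intensities survive the simulate/assign cycle
  m2 <- merge(ft$nodes[c("efp", "rel_intensity")],
              fx$table[c("efp", "rel_intensity")], by = "efp")
  expect_equal(m2$rel_intensity.x, m2$rel_intensity.y, tolerance = 1e-6)
})

test_that("assigned trees are hierarchy-sound", {
  ft <- assign_tree(glut_tree(seed = 9, mass_sigma_ppm = 2, artifact_rate = 2))
  expect_silent(validate_fragmentation_tree(ft))
  for (i in seq_len(nrow(ft$nodes))) {
    parts <- strsplit(ft$nodes$efp[i], "||", fixed = TRUE)[[1]]
    expect_identical(length(parts), as.integer(ft$nodes$ms_level[i]))
    if (length(parts) > 1) {
      loss <- subtract_formula(parts[length(parts) - 1], parts[length(parts)])
      expect_true(all(unclass(loss) >= 0))
    }
  }
})

test_that("peaks with no formula under the cap are dropped as artifacts", {
  tree <- glut_tree()
  # inject a mass with no CHNOPS sub-formula of the precursor within 6 ppm
  ms2 <- names(which(vapply(tree$scans, function(s) s$ms_level, integer(1)) == 2))[1]
  tree$scans[[ms2]]$peaks <- rbind(tree$scans[[ms2]]$peaks,
                                   data.frame(mz = 298.0, intensity = 5e4,
                                              rel_intensity = NA))
  ft <- assign_tree(tree)
  expect_equal(nrow(ft$nodes), 21)
  expect_false(any(abs(ft$nodes$observed_mz - 298.0) < 0.01))
  expect_match(ft$log, "no formula under cap", all = FALSE)
})

test_that("an MS1-only spectrum tree yields a single-node tree", {
  s <- scan("1", 1, data.frame(mz = 308.09093, intensity = 1e6))
  tree <- link_precursors(list(s))[[1]]
  ft <- assign_tree(tree, "C10H18N3O6S")
  expect_identical(efp_strings(ft), "C10H18N3O6S1")
})

test_that("consensus applies the inclusive presence threshold", {
  # EFP x: 2/5 trees (= 40%, retained); y: 1/5 (dropped); z: 5/5, sd of rel
  trees <- list(
    fake_ftree(c("R1||A1", "R1||B1"), c(50, 10)),
    fake_ftree(c("R1||A1", "R1||B1"), c(60, 20)),
    fake_ftree("R1||A1", 40),
    fake_ftree("R1||A1", 50),
    fake_ftree(c("R1||A1", "R1||C1"), c(50, 30))
  )
  cs <- consensus(trees, min_fraction = 0.4)
  expect_true("R1||B1" %in% cs$entries$efp)      # exactly 40%
  expect_false("R1||C1" %in% cs$entries$efp)     # 20%
  b <- cs$entries[cs$entries$efp == "R1||B1", ]
  expect_equal(b$presence_fraction, 0.4)
  expect_equal(b$mean_rel_intensity, 15)
  expect_equal(b$sd_rel_intensity, stats::sd(c(10, 20)))
  a <- cs$entries[cs$entries$efp == "R1||A1", ]
  expect_equal(a$presence_fraction, 1)
  root <- cs$entries[cs$entries$efp == "R1", ]
  expect_equal(root$sd_rel_intensity, 0)
})

test_that("consensus retention is monotone in min_fraction", {
  withr::with_seed(13, {
    trees <- lapply(1:6, function(i) {
      fake_ftree(paste0("R1||X", sample(1:8, sample(2:6, 1))))
    })
    sizes <- vapply(seq(0, 1, by = 0.1), function(mf) {
      nrow(consensus(trees, mf)$entries)
    }, numeric(1))
    expect_true(all(diff(sizes) <= 0))
  })
})

test_that("consensus refuses mixed precursors", {
  expect_error(consensus(list(fake_ftree("R1||A1", root = "R1"),
                              fake_ftree("R2||A1", root = "R2"))),
               "identical root")
})

test_that("JSON export round trips and is byte-deterministic", {
  ft <- assign_tree(glut_tree())
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  export_json(ft, p1)
  export_json(ft, p2)
  expect_identical(readLines(p1), readLines(p2))
  back <- import_json(p1)
  expect_identical(efp_strings(back), efp_strings(ft))
  expect_equal(back$nodes$rel_intensity, ft$nodes$rel_intensity)
})

test_that("CML export lists one molecule per EFP with parent links", {
  ft <- assign_tree(glut_tree())
  path <- withr::local_tempfile(fileext = ".cml")
  export_cml(ft, path)
  doc <- xml2::read_xml(path)
  mols <- xml2::xml_find_all(doc, "//*[local-name()='molecule']")
  expect_length(mols, 21)
  # every non-root molecule resolves its parent reference
  ids <- xml2::xml_attr(mols, "id")
  parents <- xml2::xml_attr(mols, "parentRef")
  expect_identical(sum(is.na(parents)), 1L)
  expect_true(all(parents[!is.na(parents)] %in% ids))
  peaks <- xml2::xml_find_all(doc, "//*[local-name()='peak']")
  expect_length(peaks, 21)

  cs <- consensus(list(ft, ft))
  path2 <- withr::local_tempfile(fileext = ".cml")
  export_cml(cs, path2)
  doc2 <- xml2::read_xml(path2)
  expect_length(xml2::xml_find_all(doc2, "//*[local-name()='molecule']"), 21)
})
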