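c5b <- parse_chain("G3G4G3G4G")
clean_cfg <- function(seed) {
  spectrum_sim_config(mz_jitter_sd = 0, n_noise_peaks = 0, seed = seed)
}

test_that("peak classification maps intensity to the strong/weak/absent vocabulary", {
  sp <- peak_list(c(329.2, 401.2, 533.3), c(0.02, 0.05, 0.6))
  expect_equal(as.character(classify_peak(sp, 533.3)), "present_strong")
  expect_equal(as.character(classify_peak(sp, 401.2)), "present_weak")
  expect_equal(as.character(classify_peak(sp, 809.4)), "absent")
  expect_equal(attr(classify_peak(sp, 809.4), "intensity"), 0)

  border <- peak_list(c(300), c(1)) # single peak; add one borderline
  border <- peak_list(c(300, 500), c(1, 0.2))
  cls <- classify_peak(border, 500)
  expect_equal(as.character(cls), "present_weak")
  expect_true(attr(cls, "borderline"))

  bad <- cid_thresholds()
  bad$weak_max <- 0.5
  bad$strong_min <- 0.4
  expect_error(classify_peak(sp, 533.3, thresholds = bad), "weak_max")
})

test_that("the DP-5 cellobiosyl spectrum is called G3G4G3G4G", {
  sp <- simulate_spectrum(c5b, clean_cfg(2))
  inf <- infer_structure(sp, 5)
  expect_false(inf$ambiguous)
  expect_equal(to_notation(inf$chain), "G3G4G3G4G")
  expect_true(all(inf$linkages$confidence > 0.5))

  # with comparative references the call is unchanged and fully concordant
  refs <- make_reference_fixtures(clean_cfg(20))
  inf2 <- infer_structure(sp, 5, references = refs)
  expect_equal(to_notation(inf2$chain), "G3G4G3G4G")
  expect_gte(min(inf2$linkages$confidence), min(inf$linkages$confidence))
})

test_that("homopolymer controls are recovered", {
  sp14 <- simulate_spectrum(parse_chain("G4G4G4G4G"), clean_cfg(3))
  expect_equal(to_notation(infer_structure(sp14, 5)$chain), "G4G4G4G4G")
  sp13 <- simulate_spectrum(parse_chain("G3G3G3G3G"), clean_cfg(4))
  expect_equal(to_notation(infer_structure(sp13, 5)$chain), "G3G3G3G3G")
})

test_that("all 16 DP-5 linkage vectors are recovered from clean spectra", {
  grid <- as.matrix(expand.grid(rep(list(c(3L, 4L)), 4L)))
  for (r in seq_len(nrow(grid))) {
    truth <- glucan_chain(grid[r, ])
    sp <- simulate_spectrum(truth, clean_cfg(100 + r))
    inf <- infer_structure(sp, 5)
    expect_false(inf$ambiguous)
    expect_equal(to_notation(inf$chain), to_notation(truth))
  }
})

test_that("confidence is monotone in the number of concordant diagnostics", {
  sp <- simulate_spectrum(c5b, clean_cfg(5))
  inf <- infer_structure(sp, 5)
  expect_equal(inf$linkages$confidence, rep(1, 4))  # clean: all concordant

  # deleting the V_3 peak removes one concordant linkage-2 diagnostic; the
  # call survives on the remaining evidence but linkage-2 confidence drops
  keep <- abs(sp$peaks$mz - fragment_mz(c5b, "V", 3)) > 0.5
  sp2 <- peak_list(sp$peaks$mz[keep], sp$peaks$intensity[keep],
                   precursor_mz = sp$precursor_mz)
  inf2 <- infer_structure(sp2, 5)
  expect_equal(to_notation(inf2$chain), "G3G4G3G4G")
  expect_lt(inf2$linkages$confidence[2], inf$linkages$confidence[2])
})

test_that("degenerate scoring reports an explicit tie, not a winner", {
  sp <- simulate_spectrum(c5b, clean_cfg(6))
  flat <- cid_thresholds()
  flat$w_presence <- 0
  flat$w_category <- 0
  flat$w_intensity <- 0
  inf <- infer_structure(sp, 5, thresholds = flat)
  expect_true(inf$ambiguous)
  expect_null(inf$chain)
  expect_length(inf$co_optimal, 16L)
  rep_lines <- evidence_report(inf)
  expect_match(rep_lines[length(rep_lines)], "ambiguous")
  expect_match(rep_lines[length(rep_lines)], "G3G4G3G4G")
})

test_that("a PMAA profile constraint is never contradicted", {
  set.seed(77)
  for (i in 1:10) {
    truth <- random_chain(5L)
    prof <- predict_pmaa(truth)
    sp <- simulate_spectrum(truth, clean_cfg(500 + i))
    inf <- infer_structure(sp, 5, profile = prof)
    expect_false(inf$ambiguous)
    expect_equal(predict_pmaa(inf$chain)$values, prof$values)
  }
  # an impossible constraint errors out instead of guessing
  sp <- simulate_spectrum(c5b, clean_cfg(9))
  expect_error(infer_structure(sp, 4, profile = linkage_profile(1, 3, 0, 1, 0)),
               "no candidate")
})

test_that("the evidence report walks the chain nonreducing to reducing", {
  sp <- simulate_spectrum(c5b, clean_cfg(10))
  lines <- evidence_report(infer_structure(sp, 5))
  expect_match(lines[1], "^linkage 1: D_1/E_1/G_1")
  expect_match(lines[1], "implies a 1,3")
  pos <- as.integer(sub("^linkage (\\d).*", "\\1", grep("^linkage", lines, value = TRUE)))
  expect_true(!is.unsorted(pos))
  expect_match(lines[length(lines)], "call: G3G4G3G4G")
})

test_that("dp bounds and empty spectra are rejected", {
  sp <- simulate_spectrum(c5b, clean_cfg(11))
  expect_error(infer_structure(sp, 2), "3..8")
  expect_error(infer_structure(sp, 9), "3..8")
  expect_error(infer_structure(peak_list(numeric(), numeric()), 5), "empty")
})
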