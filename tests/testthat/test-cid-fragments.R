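c5b <- parse_chain("G3G4G3G4G")
cello5 <- parse_chain("G4G4G4G4G")
lam5 <- parse_chain("G3G3G3G3G")

test_that("cross-ring 3,5A feasibility follows the 4-linkage rule", {
  fr <- enumerate_fragments(c5b)
  a <- fr[fr$series == "A35", ]
  expect_equal(a$feasibility[a$index == 2], "infeasible")
  expect_equal(a$feasibility[a$index == 3], "feasible_strong")
  expect_equal(a$feasibility[a$index == 4], "infeasible")
  expect_equal(a$feasibility[a$index == 5], "feasible_strong")
  expect_equal(a$mz[a$index == 3], 533.4, tolerance = 1 / 533)

  frc <- enumerate_fragments(cello5)
  expect_true(all(frc$feasibility[frc$series == "A35"] == "feasible_strong"))
  frl <- enumerate_fragments(lam5)
  expect_true(all(frl$feasibility[frl$series == "A35"] == "infeasible"))
})

test_that("elimination-ion feasibility encodes the comparative pattern", {
  fr <- enumerate_fragments(c5b)
  pick <- function(s, i) fr$feasibility[fr$series == s & fr$index == i]
  expect_equal(pick("V", 4), "infeasible")       # diagnoses linkage 1 (1,3)
  expect_equal(pick("V", 3), "feasible_strong")  # linkage 2 (1,4)
  expect_equal(pick("V", 2), "feasible_weak")    # linkage 3 (1,3)
  expect_equal(pick("D", 1), "feasible_strong")  # D1 enhanced for 1,3
  expect_equal(pick("E", 1), "feasible_weak")
  expect_equal(pick("D", 4), "infeasible")       # linkage 3 is 1,3
  expect_equal(pick("D", 3), "feasible_strong")  # linkage 2 is 1,4
  expect_equal(pick("X02", 2), "feasible_weak")  # linkage-independent

  frc <- enumerate_fragments(cello5)
  expect_equal(frc$feasibility[frc$series == "D" & frc$index == 1],
               "feasible_weak")
  expect_equal(frc$feasibility[frc$series == "E" & frc$index == 1],
               "feasible_strong")
})

test_that("series truncate at the chain bounds", {
  fr2 <- enumerate_fragments(parse_chain("G3G"))
  expect_true(all(fr2$index[fr2$series == "A35"] == 2L))
  expect_false(any(fr2$series == "V"))           # no interior V ions at DP 2
  expect_true(all(fr2$index[fr2$series %in% c("B", "C", "Y", "Z")] == 1L))
  expect_error(enumerate_fragments(parse_chain("G")), "DP 2..10")
  expect_error(fragment_mz(c5b, "A35", 6), "valid: 2..5")
  expect_error(fragment_mz(c5b, "V", 1), "valid: 2..4")
  expect_error(fragment_mz(c5b, "Q", 1))
})

test_that("fragment m/z values agree with the printed pentasaccharide anchors", {
  anchors <- data.frame(
    series = c("D", "E", "A35", "X02", "A35", "V", "V", "A35", "D", "A35", "V"),
    index  = c(1L, 1L, 2L, 2L, 3L, 3L, 2L, 4L, 4L, 5L, 4L),
    mz     = c(227.3, 211.3, 329.4, 519.4, 533.4, 605.4, 401.4, 737.4, 839.4,
               941.4, 809.4))
  for (r in seq_len(nrow(anchors))) {
    expect_equal(fragment_mz(c5b, anchors$series[r], anchors$index[r]),
                 anchors$mz[r], tolerance = 1.0 / anchors$mz[r],
                 label = paste0(anchors$series[r], "_", anchors$index[r]))
  }
})

test_that("same-series spacing is exactly one permethylated residue mass", {
  for (conv in c("monoisotopic", "average")) {
    res <- mass_constants(conv)[["residue_perme"]]
    for (ch in list(c5b, cello5, lam5, parse_chain("G4G3G4G"))) {
      fr <- enumerate_fragments(ch, conv)
      for (s in unique(fr$series)) {
        sub <- fr[fr$series == s, ]
        sub <- sub[order(sub$index), ]
        if (nrow(sub) >= 2L) {
          expect_equal(diff(sub$mz) / diff(sub$index), rep(res, nrow(sub) - 1L),
                       tolerance = 1e-12)
        }
      }
    }
  }
  # the anchored exploratory mode rides the same invariant
  expect_equal(fragment_mz_anchored("A35", 5, 3, fragment_mz(c5b, "A35", 3)),
               fragment_mz(c5b, "A35", 5), tolerance = 1e-12)
})

test_that("E1 and G1 are isobaric, one oxygen below D1", {
  e1 <- fragment_mz(c5b, "E", 1)
  g1 <- fragment_mz(c5b, "G", 1)
  d1 <- fragment_mz(c5b, "D", 1)
  expect_identical(e1, g1)
  expect_equal(d1 - e1, 16.00, tolerance = 0.3 / 16)
  expect_equal(fragment_mz(c5b, "D", 1, "average") -
                 fragment_mz(c5b, "E", 1, "average"), 16.00,
               tolerance = 0.3 / 16)
})

test_that("annotation assigns all real peaks and never the infeasible ions", {
  cfg <- spectrum_sim_config(mz_jitter_sd = 0, n_noise_peaks = 0, seed = 31)
  sp <- simulate_spectrum(c5b, cfg)
  ann <- annotate_spectrum(sp, c5b)
  expect_true(all(!is.na(ann$ion)))
  expect_false(any(ann$ion %in% c("A35_2", "V_4", "D_4", "A35_4", "D_2")))

  empty <- peak_list(numeric(), numeric())
  ann0 <- annotate_spectrum(empty, c5b)
  expect_equal(nrow(ann0), 0L)

  # cross-annotation flags the mismatch: the cellopentaose-only A35_2 peak
  # finds no home on the all-1,3 chain
  spc <- simulate_spectrum(cello5, cfg)
  ann_x <- annotate_spectrum(spc, lam5)
  a2 <- which.min(abs(ann_x$mz - fragment_mz(cello5, "A35", 2)))
  expect_true(is.na(ann_x$ion[a2]))
})

test_that("peak lists round-trip through TSV and MGF", {
  cfg <- spectrum_sim_config(mz_jitter_sd = 0, n_noise_peaks = 0, seed = 8)
  sp <- simulate_spectrum(c5b, cfg)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_peaklist(sp, tsv)
  back <- read_peaklist(tsv)
  expect_equal(back$peaks$mz, sp$peaks$mz, tolerance = 1e-4)
  expect_equal(back$precursor_mz, sp$precursor_mz, tolerance = 1e-4)

  mgf <- withr::local_tempfile(fileext = ".mgf")
  write_mgf(sp, mgf)
  back2 <- read_mgf(mgf)
  expect_equal(back2$peaks$mz, sp$peaks$mz, tolerance = 1e-4)
  expect_equal(back2$metadata$title, "G3G4G3G4G")
})
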