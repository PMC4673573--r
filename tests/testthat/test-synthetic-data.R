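test_that("deterministic parameter corners produce the expected chains", {
  p <- mlg_params(p_cellobiosyl = 0, triosyl_tetraosyl_ratio = c(1, 0),
                  units_per_chain = 2L, seed = 1)
  pop <- generate_mlg(p, 5)
  expect_true(all(vapply(pop, to_notation, character(1)) == "G4G4G3G4G4G"))

  expect_error(mlg_params(p_cellobiosyl = 1, units_per_chain = 1L, seed = 1),
               "impossible")
  expect_error(mlg_params(units_per_chain = 5L), "seed")
})

test_that("generation is reproducible under a fixed seed", {
  p <- mlg_params(units_per_chain = 50L, seed = 33)
  a <- generate_mlg(p, 10)
  b <- generate_mlg(p, 10)
  expect_identical(lapply(a, to_notation), lapply(b, to_notation))
  expect_identical(attr(a, "unit_counts"), attr(b, "unit_counts"))
})

test_that("realized unit composition matches the parameters", {
  p <- mlg_params(p_cellobiosyl = 0.01,
                  triosyl_tetraosyl_ratio = c(0.697, 0.303),
                  units_per_chain = 2000L, seed = 12)
  pop <- generate_mlg(p, 10)
  tally <- attr(pop, "unit_counts")
  n_units <- sum(tally)
  n_draws <- n_units - tally[["forced_triosyl"]]

  # cellobiosyl frequency among free draws: binomial(p = 0.01), 3 SE band
  se_cb <- sqrt(0.01 * 0.99 / n_draws)
  expect_lt(abs(tally[["cellobiosyl"]] / n_draws - 0.01), 3 * se_cb)
  # the realized cellobiosyl unit frequency stays under the 2% bound
  expect_lt(tally[["cellobiosyl"]] / n_units, 0.02)

  # triosyl : tetraosyl among free non-cellobiosyl draws
  n_free <- tally[["cellotriosyl"]] + tally[["cellotetraosyl"]]
  se_t <- sqrt(0.697 * 0.303 / n_free)
  expect_lt(abs(tally[["cellotriosyl"]] / n_free - 0.697), 3 * se_t)

  # every generated chain survives the notation round trip
  for (ch in pop[1:3]) {
    expect_true(parse_chain(to_notation(ch)) == ch)
  }
})

test_that("every cellobiosyl unit sits on the nonreducing side of a triosyl", {
  p <- mlg_params(p_cellobiosyl = 0.1, units_per_chain = 100L, seed = 9)
  pop <- generate_mlg(p, 5)
  for (ch in pop) {
    s <- to_notation(ch)
    # a cellobiosyl unit reads 3G4G3 (or starts the chain as ^G4G3);
    # the forced follower makes the next unit G4G4G3 / ...$
    hits <- gregexpr("(?<=3)G4G3|^G4G3", s, perl = TRUE)[[1]]
    if (hits[1] == -1L) next
    for (h in hits) {
      follower <- substr(s, h + 4L, h + 9L)
      expect_match(follower, "^G4G4G(3|$)") # triosyl: exactly two 1,4 bonds
    }
  }
})

test_that("GH12 digestion of a forced population isolates the cellobiosyl
           motif as G3G4G3G4G", {
  p <- mlg_params(units_per_chain = 500L, seed = 21)
  pop <- generate_mlg(p, 10)
  tally <- attr(pop, "unit_counts")
  r <- digest_population(pop, shipped_rulesets("GH12_aniger"))
  dp5 <- r$products[r$products$dp == 5L, ]
  # grammar motif analysis: an internal DP-5 product must span
  # [unit end]-3-[cellobiosyl]-3-[triosyl start], i.e. G3G4G3G4G; any other
  # DP-5 species can only be a chain-terminal artifact (<= 1 per chain)
  expect_lte(abs(product_count(r, "G3G4G3G4G") - tally[["cellobiosyl"]]),
             length(pop))
  other <- dp5[dp5$notation != "G3G4G3G4G", ]
  expect_lte(sum(other$count), length(pop))
})

test_that("long 1,4 stretches appear only when enabled", {
  p <- mlg_params(long_stretch = list(p = 0.05, dp_range = c(6, 9)),
                  units_per_chain = 200L, seed = 14)
  pop <- generate_mlg(p, 5)
  expect_gt(attr(pop, "unit_counts")[["long_stretch"]], 0)
  # a long stretch leaves a >= 5-run of 1,4 bonds somewhere
  runs <- vapply(pop, function(ch) {
    r <- rle(ch$linkages)
    max(r$lengths[r$values == 4L])
  }, integer(1))
  expect_gt(max(runs), 4L)
})

test_that("clean simulated spectra hit theoretical positions exactly and
           omit infeasible ions", {
  c5b <- parse_chain("G3G4G3G4G")
  cfg <- spectrum_sim_config(mz_jitter_sd = 0, n_noise_peaks = 0, seed = 41)
  sp <- simulate_spectrum(c5b, cfg)
  feas <- enumerate_fragments(c5b)
  feas <- feas[feas$feasibility != "infeasible", ]
  for (mz in unique(round(feas$mz, 6))) {
    expect_true(any(abs(sp$peaks$mz - mz) < 1e-9))
  }
  for (bad in c(fragment_mz(c5b, "A35", 2), fragment_mz(c5b, "V", 4))) {
    expect_false(any(abs(sp$peaks$mz - bad) < 1.0))
  }
  # reproducibility
  sp2 <- simulate_spectrum(c5b, cfg)
  expect_identical(sp$peaks, sp2$peaks)
})

test_that("reference fixtures behave like their homopolymers and regenerate
           byte-identically", {
  refs <- make_reference_fixtures()
  expect_equal(refs$all14$precursor_mz, 1089.5, tolerance = 0.1 / 1089)

  # laminaripentaose reference carries no 3,5A-series peak at all
  a_mz <- vapply(2:5, function(i) series_mz_for_test("A35", i), numeric(1))
  for (mz in a_mz) {
    expect_false(any(abs(refs$all13$peaks$mz - mz) < 1.0))
    expect_true(any(abs(refs$all14$peaks$mz - mz) < 0.01))
  }

  # D1 weaker than E1/G1 for the all-1,4 reference, reversed for all-1,3
  d1 <- series_mz_for_test("D", 1)
  e1 <- series_mz_for_test("E", 1)
  int_at <- function(pl, mz) {
    i <- which(abs(pl$peaks$mz - mz) < 0.01)
    if (length(i)) pl$peaks$intensity[i] else 0
  }
  expect_lt(int_at(refs$all14, d1), int_at(refs$all14, e1))
  expect_gt(int_at(refs$all13, d1), int_at(refs$all13, e1))

  # shipped fixture files regenerate byte-identically from the pinned seeds
  t14 <- withr::local_tempfile(fileext = ".tsv")
  t13 <- withr::local_tempfile(fileext = ".tsv")
  write_peaklist(refs$all14, t14)
  write_peaklist(refs$all13, t13)
  expect_identical(readLines(t14),
                   readLines(test_path_extdata("cellopentaose_ref_synthetic.tsv")))
  expect_identical(readLines(t13),
                   readLines(test_path_extdata("laminaripentaose_ref_synthetic.tsv")))
})
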