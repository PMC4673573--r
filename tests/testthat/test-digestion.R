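gh12 <- shipped_rulesets("GH12_aniger")
gh16 <- shipped_rulesets("GH16_trichoderma")
gh17 <- shipped_rulesets("GH17_barley")

test_that("subsite clauses pick out the documented cleavable bonds", {
  expect_equal(cleavable_bonds(parse_chain("G3G4G3G4G"), gh16), c(2L, 4L))
  expect_length(cleavable_bonds(parse_chain("G3G4G4G"), gh16), 0L)
  expect_length(cleavable_bonds(parse_chain("G4G4G4G4G"), gh17), 0L)
  expect_length(cleavable_bonds(parse_chain("G4G4G4G4G"), gh16), 0L)
  # smallest GH16 substrate with a cellobiosyl context
  expect_equal(cleavable_bonds(parse_chain("G3G4G3G"), gh16), 2L)
  expect_length(cleavable_bonds(parse_chain("G3G4G"), gh16), 0L)
})

test_that("GH16 limit digestion of the DP-5 cellobiosyl oligosaccharide", {
  r <- limit_digest(parse_chain("G3G4G3G4G"), gh16)
  expect_equal(product_count(r, "G3G"), 2)
  expect_equal(product_count(r, "G"), 1)
  expect_equal(nrow(r$products), 2L)
  expect_equal(r$cleavage_events, 2)

  r4 <- limit_digest(parse_chain("G3G4G3G"), gh16)
  expect_equal(r4$products$notation, "G3G")
  expect_equal(r4$products$count, 2)

  r3 <- limit_digest(parse_chain("G3G4G"), gh16)
  expect_equal(r3$products$notation, "G3G4G")
  expect_equal(r3$cleavage_events, 0)
})

test_that("GH12 converts canonical MLG to 1,3-leading tri/tetra products", {
  set.seed(3)
  sizes <- c(sample(c(3L, 4L), 30, replace = TRUE), 3L)
  r <- limit_digest(chain_from_units(sizes), gh12)
  internal <- r$products[grepl("^G3", r$products$notation), ]
  expect_true(all(internal$notation %in% c("G3G4G", "G3G4G4G")))
  # one cleavage per internal unit boundary offset: units - 1 products lead
  # with the 1,3 bond; the single remaining product is the nonreducing-
  # terminal stub (G4G or G4G4G)
  expect_equal(sum(internal$count), length(sizes) - 1)
  stubs <- r$products[!grepl("^G3", r$products$notation), ]
  expect_equal(sum(stubs$count), 1)
  expect_true(all(stubs$notation %in% c("G4G", "G4G4G")))
})

test_that("GH12 leaves its own limit products intact", {
  for (s in c("G3G4G", "G3G4G4G", "G3G4G3G4G")) {
    r <- limit_digest(parse_chain(s), gh12)
    expect_equal(r$products$notation, s)
    expect_equal(r$cleavage_events, 0)
  }
})

test_that("rule-set concordance: substrate specificities across enzymes", {
  laminarin <- glucan_chain(rep(3L, 19))   # all-1,3 DP 20
  cellulose <- glucan_chain(rep(4L, 19))
  mlg <- chain_from_units(c(3L, 4L, 3L, 3L, 4L, 3L))
  mlg_cb <- chain_from_units(c(3L, 4L, 2L, 3L, 3L, 4L, 3L))

  expect_gt(limit_digest(laminarin, gh16)$cleavage_events, 0)
  expect_equal(limit_digest(cellulose, gh16)$cleavage_events, 0)
  expect_equal(limit_digest(mlg, gh16)$cleavage_events, 0)    # no cellobiosyl
  expect_gt(limit_digest(mlg_cb, gh16)$cleavage_events, 0)    # cellobiosyl site

  expect_gt(limit_digest(laminarin, gh17)$cleavage_events, 0)
  expect_equal(limit_digest(mlg, gh17)$cleavage_events, 0)
  expect_equal(limit_digest(mlg_cb, gh17)$cleavage_events, 0)
  expect_equal(limit_digest(cellulose, gh17)$cleavage_events, 0)

  # GH17's smallest substrate is laminaritriose
  expect_equal(limit_digest(parse_chain("G3G3G"), gh17)$products$notation,
               c("G", "G3G"))
  expect_equal(limit_digest(parse_chain("G3G"), gh17)$cleavage_events, 0)

  # lichenase releases 1,3-terminated products like G4G3G (triosyl) and
  # G4G4G3G (tetraosyl); only the nonreducing-end stub lacks the 1,3 bond
  lich <- limit_digest(mlg, shipped_rulesets("GH_lichenase"))
  expect_gt(product_count(lich, "G4G3G"), 0)
  expect_gt(product_count(lich, "G4G4G3G"), 0)
})

test_that("digest bookkeeping: conservation, fractions, reducing ends", {
  ch <- chain_from_units(c(3L, 2L, 3L, 4L, 3L))
  r <- limit_digest(ch, gh16)
  expect_equal(total_residues(r), ch$n_residues)
  expect_equal(sum(r$dp_mass_fraction), 1, tolerance = 1e-9)
  expect_equal(r$cleavage_events, sum(r$products$count) - 1)
})

test_that("digest_population aggregates and rejects empty input", {
  pop <- list(parse_chain("G3G"), parse_chain("G3G"))
  r <- digest_population(pop, gh16)
  expect_equal(r$dp_mass_fraction[["2"]], 1.0)
  expect_equal(r$products$notation, "G3G")
  expect_error(digest_population(list(), gh16), "nonempty")
})

test_that("limit digestion is idempotent on its own products", {
  set.seed(42)
  for (i in 1:20) {
    ch <- random_chain(sample(2:40, 1L))
    rules <- random_ruleset()
    r1 <- limit_digest(ch, rules)
    again <- digest_population(product_chains(r1), rules)
    # digesting each unique product again changes nothing
    expect_equal(again$cleavage_events, 0)
    expect_equal(sort(again$products$notation), sort(r1$products$notation))
  }
})

test_that("mass conservation holds for random chain x rule-set pairs", {
  set.seed(99)
  for (i in 1:100) {
    ch <- random_chain(sample(1:50, 1L))
    r <- limit_digest(ch, random_ruleset())
    expect_equal(total_residues(r), ch$n_residues)
    expect_equal(r$cleavage_events, sum(r$products$count) - 1)
  }
})

test_that("relaxing a rule-set clause never shrinks the cleavable set", {
  relaxations <- function(rules) {
    out <- list()
    if (!setequal(rules$cleavable_linkages, c(3L, 4L))) {
      r <- rules; r$cleavable_linkages <- c(3L, 4L); out <- c(out, list(r))
    }
    if (rules$required_linkage_minus2_minus1 != "any" ||
        rules$required_occupancy_minus2) {
      r <- rules
      r$required_linkage_minus2_minus1 <- "any"
      r$required_occupancy_minus2 <- FALSE
      out <- c(out, list(r))
    }
    if (rules$required_linkage_plus1_plus2 != "any" || !rules$plus2_may_be_empty) {
      r <- rules
      r$required_linkage_plus1_plus2 <- "any"
      r$plus2_may_be_empty <- TRUE
      out <- c(out, list(r))
    }
    if (rules$min_substrate_dp > 2L) {
      r <- rules; r$min_substrate_dp <- 2L; out <- c(out, list(r))
    }
    out
  }
  set.seed(17)
  for (i in 1:50) {
    ch <- random_chain(sample(2:30, 1L))
    rules <- random_ruleset()
    base <- cleavable_bonds(ch, rules)
    for (relaxed in relaxations(rules)) {
      expect_true(all(base %in% cleavable_bonds(ch, relaxed)))
    }
  }
})

test_that("number-average DP behaves as an endo-action readout", {
  r <- limit_digest(parse_chain("G3G4G3G4G"), gh16)
  expect_equal(number_average_dp(r), 5 / 3)

  intact <- limit_digest(glucan_chain(rep(4L, 99)), gh16)
  expect_equal(number_average_dp(intact), 100)

  pop <- generate_mlg(mlg_params(p_cellobiosyl = 0.02, units_per_chain = 200L,
                                 seed = 5), 20)
  expect_lt(number_average_dp(digest_population(pop, gh16)),
            number_average_dp(digest_population(pop, gh17)))
  # GH17 leaves the MLG population intact entirely
  expect_equal(digest_population(pop, gh17)$cleavage_events, 0)
})

test_that("sequential mode exposes both documented routes and their distinct
           end points", {
  c5b <- parse_chain("G3G4G3G4G")
  seen <- character()
  for (s in 1:20) {
    sq <- sequential_digest(c5b, gh16, seed = s)
    first <- paste(sq$route[[1]], collapse = "+")
    seen <- c(seen, first)
    final <- sq$result$products
    if (first == "G+G3G4G3G") {
      # route via G3G4G3G reaches the limit set: 2x laminaribiose + glucose
      expect_equal(final$notation, c("G", "G3G"))
      expect_equal(final$count, c(1, 2))
    } else {
      # the alternative first cut strands G3G4G below the DP-4 minimum
      expect_equal(first, "G3G+G3G4G")
      expect_equal(final$notation, c("G3G", "G3G4G"))
      expect_equal(final$count, c(1, 1))
    }
    expect_equal(total_residues(sq$result), 5L)
  }
  # both documented first cleavages occur across seeds
  expect_setequal(unique(seen), c("G+G3G4G3G", "G3G+G3G4G"))
  # the simultaneous schedule is route-free and reaches the limit set
  ref <- limit_digest(c5b, gh16)
  expect_equal(ref$products$notation, c("G", "G3G"))
})

test_that("rule sets survive a JSON round trip", {
  path <- withr::local_tempfile(fileext = ".json")
  write_ruleset(gh16, path)
  back <- read_ruleset(path)
  expect_equal(unclass(back), unclass(gh16))
  expect_equal(cleavable_bonds(parse_chain("G3G4G3G4G"), back), c(2L, 4L))
})

test_that("max_rounds caps the digest for partial-digest snapshots", {
  lam <- glucan_chain(rep(3L, 15))
  partial <- limit_digest(lam, gh17, max_rounds = 1)
  full <- limit_digest(lam, gh17)
  expect_lt(full$number_average_dp, partial$number_average_dp + 1e-12)
  expect_equal(total_residues(partial), 16L)
})
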