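# Shared generators for property-style tests. All callers fix the RNG seed
# themselves (withr::with_seed is not used to keep the dependency footprint
# at testthat only).

random_chain <- function(dp) {
  if (dp == 1L) return(glucan_chain())
  glucan_chain(sample(c(3L, 4L), dp - 1L, replace = TRUE))
}

random_ruleset <- function() {
  enzyme_ruleset(
    name = "random",
    cleavable_linkages = sample(list(3L, 4L, c(3L, 4L)), 1L)[[1]],
    required_linkage_minus2_minus1 = sample(
      c("L3", "L4", "any", "must_be_chain_end"), 1L),
    required_occupancy_minus2 = sample(c(TRUE, FALSE), 1L),
    required_linkage_plus1_plus2 = sample(c("L3", "L4", "any"), 1L),
    plus2_may_be_empty = sample(c(TRUE, FALSE), 1L),
    min_substrate_dp = sample(2:6, 1L)
  )
}

# Canonical MLG chain built from an explicit unit-size sequence
# (3 = cellotriosyl, 4 = cellotetraosyl, 2 = cellobiosyl): all intra-unit
# bonds 1,4, single 1,3 bonds between units.
chain_from_units <- function(sizes) {
  lv <- integer(0)
  for (k in seq_along(sizes)) {
    lv <- c(lv, rep(4L, sizes[k] - 1L))
    if (k < length(sizes)) lv <- c(lv, 3L)
  }
  glucan_chain(lv)
}

total_residues <- function(result) sum(result$products$dp * result$products$count)

# Fragment positions are composition-only (linkage never shifts m/z), so any
# DP-5 chain provides them; the homopolymer has every series feasible.
series_mz_for_test <- function(series, index) {
  fragment_mz(parse_chain("G4G4G4G4G"), series, index)
}

test_path_extdata <- function(file) {
  path <- system.file("extdata", file, package = "mlglucan")
  if (!nzchar(path)) stop("missing installed extdata file: ", file)
  path
}

product_count <- function(result, notation) {
  hit <- result$products$notation == notation
  if (any(hit)) result$products$count[hit] else 0
}
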