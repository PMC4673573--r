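#' Cleavable bonds under a subsite rule set
#'
#' Evaluates every glucosidic bond of `chain` against `rules` (see
#' [enzyme_ruleset()] for the clause semantics). Bond `i` joins residue `i`
#' (subsite -1) to residue `i + 1` (subsite +1); the -2/-1 linkage is bond
#' `i - 1` and the +1/+2 linkage is bond `i + 1`.
#'
#' @param chain a [glucan_chain()].
#' @param rules an [enzyme_ruleset()].
#' @return Integer vector of cleavable bond indices (possibly empty).
#' @export
#' @examples
#' cleavable_bonds(parse_chain("G3G4G3G4G"), shipped_rulesets("GH16_trichoderma"))
cleavable_bonds <- function(chain, rules) {
  stopifnot(is_glucan_chain(chain), is_enzyme_ruleset(rules))
  cleavable_bonds_lv(chain$linkages, rules)
}

# Vectorized core on a bare linkage vector (3/4 integers).
cleavable_bonds_lv <- function(lv, rules) {
  nb <- length(lv)
  if (nb == 0L || nb + 1L < rules$min_substrate_dp) return(integer())
  ok <- lv %in% rules$cleavable_linkages

  # -2/-1 clause: previous linkage (bond i-1); bond 1 has an empty -2 subsite
  prev <- c(NA_integer_, lv[-nb])
  req_m <- rules$required_linkage_minus2_minus1
  if (req_m == "must_be_chain_end") {
    ok <- ok & is.na(prev)
  } else {
    if (rules$required_occupancy_minus2) ok <- ok & !is.na(prev)
    if (req_m == "L3") ok <- ok & !is.na(prev) & prev == 3L
    if (req_m == "L4") ok <- ok & !is.na(prev) & prev == 4L
  }

  # +1/+2 clause: next linkage (bond i+1); the last bond has an empty +2
  nxt <- c(lv[-1L], NA_integer_)
  req_p <- rules$required_linkage_plus1_plus2
  if (req_p == "any") {
    if (!rules$plus2_may_be_empty) ok <- ok & !is.na(nxt)
  } else {
    want <- if (req_p == "L3") 3L else 4L
    match_p <- !is.na(nxt) & nxt == want
    if (rules$plus2_may_be_empty) match_p <- match_p | is.na(nxt)
    ok <- ok & match_p
  }
  which(ok)
}

# Split a linkage vector at the given bond indices; returns a list of
# product linkage vectors in nonreducing -> reducing order.
split_at_bonds <- function(lv, bonds) {
  n <- length(lv) + 1L
  starts <- c(1L, bonds + 1L)
  ends <- c(bonds, n)
  mapply(function(s, e) if (s >= e) integer() else lv[s:(e - 1L)],
         starts, ends, SIMPLIFY = FALSE)
}

#' Limit digestion of a single chain
#'
#' Iterated mark-and-cleave: in each round, all currently cleavable bonds of
#' every current product are cleaved simultaneously; the digest terminates
#' when no product carries a cleavable bond. This deterministic schedule
#' reaches the limit-digest product set regardless of the order in which a
#' real enzyme visits bonds. For route exploration (one bond per step, in
#' random order) see [sequential_digest()].
#'
#' @param chain a [glucan_chain()] (or a list of them, treated as the
#'   substrate pool).
#' @param rules an [enzyme_ruleset()].
#' @param max_rounds cap on mark-and-cleave rounds (default `Inf`, i.e. the
#'   true limit digest); a finite cap gives qualitative partial-digest
#'   snapshots.
#' @return A `digest_result`: list with `products` (data.frame `notation`,
#'   `dp`, `count`), `cleavage_events`, `rounds`, `dp_mass_fraction`
#'   (named numeric, fraction of total residues per product DP),
#'   `number_average_dp`, and `n_substrates`. Every product molecule carries
#'   one reducing end, so the reducing-end count equals `sum(products$count)`.
#' @export
#' @examples
#' limit_digest(parse_chain("G3G4G3G4G"), shipped_rulesets("GH16_trichoderma"))
limit_digest <- function(chain, rules, max_rounds = Inf) {
  if (is_glucan_chain(chain)) chain <- list(chain)
  stopifnot(length(chain) >= 1L, all(vapply(chain, is_glucan_chain, logical(1))),
            is_enzyme_ruleset(rules))

  active_lv <- lapply(chain, `[[`, "linkages")
  active_n <- rep(1, length(active_lv))
  n_substrates <- length(active_lv)

  done <- new.env(parent = emptyenv()) # notation -> count
  cleavages <- 0
  rounds <- 0L

  while (length(active_lv) > 0L && rounds < max_rounds) {
    # collapse identical active chains so each unique sequence is cut once
    sig <- vapply(active_lv, paste, character(1), collapse = "")
    first <- !duplicated(sig)
    counts <- vapply(sig[first], function(s) sum(active_n[sig == s]),
                     numeric(1), USE.NAMES = FALSE)
    uniq_lv <- active_lv[first]

    next_lv <- list()
    next_n <- numeric()
    cut_any <- FALSE
    for (k in seq_along(uniq_lv)) {
      lv <- uniq_lv[[k]]
      bonds <- cleavable_bonds_lv(lv, rules)
      if (length(bonds) == 0L) {
        key <- lv_notation(lv)
        done[[key]] <- (if (is.null(done[[key]])) 0 else done[[key]]) + counts[k]
      } else {
        cut_any <- TRUE
        cleavages <- cleavages + length(bonds) * counts[k]
        pieces <- split_at_bonds(lv, bonds)
        next_lv <- c(next_lv, pieces)
        next_n <- c(next_n, rep(counts[k], length(pieces)))
      }
    }
    active_lv <- next_lv
    active_n <- next_n
    if (cut_any) rounds <- rounds + 1L
  }
  # flush anything still active (only when max_rounds stopped the digest)
  if (length(active_lv) > 0L) {
    sig <- vapply(active_lv, lv_notation, character(1))
    for (k in seq_along(active_lv)) {
      done[[sig[k]]] <- (if (is.null(done[[sig[k]]])) 0 else done[[sig[k]]]) + active_n[k]
    }
  }

  notation <- ls(done)
  count <- vapply(notation, function(k) done[[k]], numeric(1), USE.NAMES = FALSE)
  dp <- (nchar(notation) + 1L) %/% 2L
  o <- order(dp, notation)
  products <- data.frame(notation = notation[o], dp = dp[o], count = count[o],
                         stringsAsFactors = FALSE)
  new_digest_result(products, cleavages, rounds, n_substrates)
}

lv_notation <- function(lv) {
  if (length(lv) == 0L) return("G")
  paste0("G", paste0(lv, "G", collapse = ""))
}

new_digest_result <- function(products, cleavage_events, rounds, n_substrates) {
  total_res <- sum(products$dp * products$count)
  total_mol <- sum(products$count)
  frac <- tapply(products$dp * products$count, products$dp, sum) / total_res
  dpf <- as.numeric(frac)
  names(dpf) <- names(frac)
  structure(
    list(
      products = products,
      cleavage_events = cleavage_events,
      rounds = rounds,
      n_substrates = n_substrates,
      dp_mass_fraction = dpf,
      number_average_dp = total_res / total_mol
    ),
    class = "digest_result"
  )
}

#' @export
print.digest_result <- function(x, ...) {
  cat(sprintf("<digest_result> %d substrate(s) -> %s product molecule(s), %s cleavage(s), %d round(s)\n",
              x$n_substrates, format(sum(x$products$count), big.mark = ","),
              format(x$cleavage_events, big.mark = ","), x$rounds))
  cat(sprintf("  number-average DP: %.3f\n", x$number_average_dp))
  show <- utils::head(x$products[order(-x$products$count), ], 10L)
  for (i in seq_len(nrow(show))) {
    cat(sprintf("  %-14s DP %2d  x %s\n", show$notation[i], show$dp[i],
                format(show$count[i], big.mark = ",")))
  }
  if (nrow(x$products) > 10L) cat(sprintf("  ... %d more product species\n",
                                          nrow(x$products) - 10L))
  invisible(x)
}

#' Products of a digest as chain objects
#' @param result a `digest_result`.
#' @return Named list of [glucan_chain()] (names = notation); multiplicities
#'   are in `result$products$count`.
#' @export
product_chains <- function(result) {
  stopifnot(inherits(result, "digest_result"))
  stats::setNames(lapply(result$products$notation, parse_chain),
                  result$products$notation)
}

#' Limit digestion of a chain population
#'
#' Aggregate of per-chain limit digests; DP mass fractions are computed over
#' all product residues of the whole population.
#'
#' @param chains nonempty list of [glucan_chain()].
#' @param rules an [enzyme_ruleset()].
#' @param max_rounds see [limit_digest()].
#' @return A `digest_result` (see [limit_digest()]).
#' @export
digest_population <- function(chains, rules, max_rounds = Inf) {
  if (is_glucan_chain(chains)) chains <- list(chains)
  if (!is.list(chains) || length(chains) == 0L) {
    stop("chains must be a nonempty list of glucan_chain objects", call. = FALSE)
  }
  limit_digest(chains, rules, max_rounds = max_rounds)
}

#' Number-average degree of polymerization
#'
#' Total residues divided by the number of product molecules: the DP
#' analogue of a number-average molecular weight, the quantity an
#' endo-acting enzyme drives down as it cleaves internally.
#'
#' @param result a `digest_result`.
#' @return Numeric scalar.
#' @export
number_average_dp <- function(result) {
  stopifnot(inherits(result, "digest_result"))
  result$number_average_dp
}

#' Sequential (single-bond-per-step) digestion
#'
#' Route-exploration mode: at each step one randomly chosen cleavable bond
#' of one randomly chosen current product is hydrolyzed. Unlike the
#' simultaneous schedule of [limit_digest()], the end point can depend on
#' the route: an early cut may strand a fragment below the enzyme's minimum
#' substrate DP. A GH16 digest of G3G4G3G4G either passes through
#' G3G4G3G + Glc and ends at two laminaribiose + glucose, or cuts
#' G3G4G + laminaribiose first and stalls there (G3G4G is below the DP-4
#' minimum) — the two documented interpretations of the product ladder.
#'
#' @param chain a [glucan_chain()].
#' @param rules an [enzyme_ruleset()].
#' @param seed integer seed (mandatory; the route is random).
#' @return List with `result` (a `digest_result`) and `route`, a list of
#'   character vectors giving the product notations after each step.
#' @export
sequential_digest <- function(chain, rules, seed) {
  stopifnot(is_glucan_chain(chain), is_enzyme_ruleset(rules))
  if (missing(seed)) stop("seed is required for sequential_digest", call. = FALSE)
  rng <- local_rng(seed)
  pool <- list(chain$linkages)
  route <- list()
  cleavages <- 0L
  repeat {
    options_per_chain <- lapply(pool, cleavable_bonds_lv, rules = rules)
    has <- which(lengths(options_per_chain) > 0L)
    if (length(has) == 0L) break
    ci <- if (length(has) == 1L) has else has[rng$int(length(has))]
    bonds <- options_per_chain[[ci]]
    b <- if (length(bonds) == 1L) bonds else bonds[rng$int(length(bonds))]
    pieces <- split_at_bonds(pool[[ci]], b)
    pool <- c(pool[-ci], pieces)
    cleavages <- cleavages + 1L
    route[[length(route) + 1L]] <- sort(vapply(pool, lv_notation, character(1)))
  }
  notation <- vapply(pool, lv_notation, character(1))
  tab <- table(notation)
  products <- data.frame(notation = names(tab),
                         dp = (nchar(names(tab)) + 1L) %/% 2L,
                         count = as.numeric(tab), stringsAsFactors = FALSE)
  products <- products[order(products$dp, products$notation), ]
  rownames(products) <- NULL
  list(result = new_digest_result(products, cleavages, rounds = cleavages,
                                  n_substrates = 1L),
       route = route)
}

# Small self-contained RNG wrapper: isolates package randomness from the
# caller's .Random.seed and gives seeded uniform/int/norm draws.
local_rng <- function(seed) {
  seed <- as.integer(seed)
  env <- new.env(parent = emptyenv())
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, globalenv())
  }
  with_state <- function(f) {
    function(...) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      assign(".Random.seed", env$state, globalenv())
      on.exit({
        env$state <- get(".Random.seed", globalenv())
        if (is.null(old)) rm(".Random.seed", envir = globalenv())
        else assign(".Random.seed", old, globalenv())
      })
      f(...)
    }
  }
  list(
    unif = with_state(stats::runif),
    norm = with_state(stats::rnorm),
    int = with_state(function(n, size = 1L) sample.int(n, size)),
    sample = with_state(sample)
  )
}
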