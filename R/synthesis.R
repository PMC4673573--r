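#' Parameters for synthetic MLG chain populations
#'
#' The generator works at the level of cellooligosaccharide units, the terms
#' in which grass MLG fine structure is described: chains are concatenations
#' of cellobiosyl (DP 2), cellotriosyl (DP 3) and cellotetraosyl (DP 4)
#' units — all intra-unit bonds 1,4 — joined by single 1,3 bonds, with an
#' optional rare long 1,4 stretch. Defaults emulate barley beta-1,3:1,4-
#' glucan: cellobiosyl draw probability 0.01 (keeping the realized
#' cellobiosyl unit frequency under the reported 2% bound), remaining draws
#' split cellotriosyl : cellotetraosyl = 0.697 : 0.303 (a literature-typical
#' barley ratio; the source material does not print one), and every
#' cellobiosyl unit forced to sit immediately on the nonreducing side of a
#' cellotriosyl unit, the placement inferred for barley. With these defaults
#' the expected DP-5 mass fraction after a GH12 limit digest is
#' `5q / (5q + (1 - q) * (0.697 * 3 + 0.303 * 4))` = 1.5% for q = 0.01.
#'
#' @param p_cellobiosyl probability that a unit draw is cellobiosyl.
#' @param triosyl_tetraosyl_ratio length-2 nonnegative weights for
#'   cellotriosyl and cellotetraosyl among non-cellobiosyl draws
#'   (renormalized).
#' @param force_triosyl_after_cellobiosyl logical; when `TRUE` (default)
#'   the unit following a cellobiosyl is always a cellotriosyl. A
#'   cellobiosyl drawn at the final unit slot is redrawn as a
#'   non-cellobiosyl unit (there is no room for the forced follower).
#' @param long_stretch optional list `list(p =, dp_range = c(lo, hi))`:
#'   probability that a draw is instead a long all-1,4 stretch and the
#'   uniform DP range of that stretch. `NULL` (default) disables it.
#' @param units_per_chain integer number of units per chain.
#' @param seed integer seed (mandatory: every population is reproducible).
#' @return An object of class `mlg_params`.
#' @export
mlg_params <- function(p_cellobiosyl = 0.01,
                       triosyl_tetraosyl_ratio = c(0.697, 0.303),
                       force_triosyl_after_cellobiosyl = TRUE,
                       long_stretch = NULL,
                       units_per_chain = 100L,
                       seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (p_cellobiosyl < 0 || p_cellobiosyl > 1) {
    stop("p_cellobiosyl must be in [0, 1]", call. = FALSE)
  }
  if (length(triosyl_tetraosyl_ratio) != 2L ||
      any(triosyl_tetraosyl_ratio < 0) || sum(triosyl_tetraosyl_ratio) <= 0) {
    stop("triosyl_tetraosyl_ratio must be two nonnegative weights", call. = FALSE)
  }
  units_per_chain <- as.integer(units_per_chain)
  if (is.na(units_per_chain) || units_per_chain < 1L) {
    stop("units_per_chain must be a positive integer", call. = FALSE)
  }
  if (p_cellobiosyl >= 1 && isTRUE(force_triosyl_after_cellobiosyl) &&
      units_per_chain == 1L) {
    stop(paste("impossible parameters: p_cellobiosyl = 1 with forcing needs",
               "at least 2 units per chain"), call. = FALSE)
  }
  if (!is.null(long_stretch)) {
    if (!all(c("p", "dp_range") %in% names(long_stretch)) ||
        long_stretch$p < 0 || long_stretch$p > 1 ||
        length(long_stretch$dp_range) != 2L ||
        long_stretch$dp_range[1] < 5 ||
        long_stretch$dp_range[2] < long_stretch$dp_range[1]) {
      stop("long_stretch must be list(p = prob, dp_range = c(lo >= 5, hi >= lo))",
           call. = FALSE)
    }
    if (long_stretch$p + p_cellobiosyl > 1) {
      stop("p_cellobiosyl + long_stretch$p must not exceed 1", call. = FALSE)
    }
  }
  structure(
    list(p_cellobiosyl = p_cellobiosyl,
         triosyl_tetraosyl_ratio = triosyl_tetraosyl_ratio / sum(triosyl_tetraosyl_ratio),
         force_triosyl_after_cellobiosyl = isTRUE(force_triosyl_after_cellobiosyl),
         long_stretch = long_stretch,
         units_per_chain = units_per_chain,
         seed = as.integer(seed)),
    class = "mlg_params"
  )
}

#' Generate a synthetic MLG chain population
#'
#' Draws `n_chains` chains of `params$units_per_chain` units each under the
#' unit-level grammar of [mlg_params()]. Unit draws are sequential so that
#' the cellobiosyl-follower forcing can be honored; two runs with the same
#' parameters (including seed) produce identical populations.
#'
#' @param params an [mlg_params()].
#' @param n_chains number of chains (>= 1).
#' @return List of [glucan_chain()] with attribute `unit_counts` (named
#'   tally of cellobiosyl / cellotriosyl / cellotetraosyl / long-stretch
#'   units, with forced units counted separately) for composition checks.
#' @export
#' @examples
#' pop <- generate_mlg(mlg_params(units_per_chain = 10, seed = 1), 3)
generate_mlg <- function(params, n_chains) {
  stopifnot(inherits(params, "mlg_params"))
  n_chains <- as.integer(n_chains)
  if (is.na(n_chains) || n_chains < 1L) stop("n_chains must be >= 1", call. = FALSE)
  rng <- local_rng(params$seed)
  q <- params$p_cellobiosyl
  p_ls <- if (is.null(params$long_stretch)) 0 else params$long_stretch$p
  w_t <- params$triosyl_tetraosyl_ratio[1]

  tally <- c(cellobiosyl = 0L, cellotriosyl = 0L, cellotetraosyl = 0L,
             long_stretch = 0L, forced_triosyl = 0L)
  nu <- params$units_per_chain
  chains <- vector("list", n_chains)
  for (ci in seq_len(n_chains)) {
    u <- rng$unif(2L * nu)  # one draw per unit + spares for the ratio draw
    sizes <- integer(nu)
    force_next <- FALSE
    for (k in seq_len(nu)) {
      if (force_next) {
        sizes[k] <- 3L
        tally["forced_triosyl"] <- tally["forced_triosyl"] + 1L
        force_next <- FALSE
        next
      }
      x <- u[k]
      cb_allowed <- !(params$force_triosyl_after_cellobiosyl && k == nu)
      if (cb_allowed && x < q) {
        sizes[k] <- 2L
        tally["cellobiosyl"] <- tally["cellobiosyl"] + 1L
        force_next <- params$force_triosyl_after_cellobiosyl
      } else if (p_ls > 0 && x < q + p_ls && !(x < q)) {
        lo <- params$long_stretch$dp_range[1]
        hi <- params$long_stretch$dp_range[2]
        sizes[k] <- lo + as.integer(floor(u[nu + k] * (hi - lo + 1L)))
        tally["long_stretch"] <- tally["long_stretch"] + 1L
      } else {
        if (u[nu + k] < w_t) {
          sizes[k] <- 3L
          tally["cellotriosyl"] <- tally["cellotriosyl"] + 1L
        } else {
          sizes[k] <- 4L
          tally["cellotetraosyl"] <- tally["cellotetraosyl"] + 1L
        }
      }
    }
    # units: (size - 1) intra-unit 1,4 bonds; single 1,3 bond between units
    lv <- integer(sum(sizes) - 1L)
    pos <- 1L
    for (k in seq_len(nu)) {
      nb <- sizes[k] - 1L
      if (nb > 0L) {
        lv[pos:(pos + nb - 1L)] <- 4L
        pos <- pos + nb
      }
      if (k < nu) {
        lv[pos] <- 3L
        pos <- pos + 1L
      }
    }
    chains[[ci]] <- glucan_chain(lv)
  }
  attr(chains, "unit_counts") <- tally
  chains
}

#' Configuration for simulated CID spectra
#'
#' @param strong_band,weak_band length-2 intensity ranges (relative to base
#'   peak) from which `feasible_strong` / `feasible_weak` ions draw their
#'   intensities; bands must be ordered (`weak_band` entirely below
#'   `strong_band`).
#' @param mz_jitter_sd standard deviation (Da) of Gaussian m/z error added
#'   to every real peak (>= 0).
#' @param n_noise_peaks number of uniform random noise peaks.
#' @param noise_max maximum noise-peak intensity.
#' @param seed integer seed (mandatory).
#' @param convention mass convention of the theoretical m/z values.
#' @return An object of class `spectrum_sim_config`.
#' @export
spectrum_sim_config <- function(strong_band = c(0.5, 1.0),
                                weak_band = c(0.02, 0.08),
                                mz_jitter_sd = 0,
                                n_noise_peaks = 0L,
                                noise_max = 0.05,
                                seed,
                                convention = c("monoisotopic", "average")) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  convention <- match.arg(convention)
  stopifnot(length(strong_band) == 2L, length(weak_band) == 2L)
  if (!(weak_band[1] <= weak_band[2] && strong_band[1] <= strong_band[2] &&
        weak_band[2] < strong_band[1])) {
    stop("bands must be ordered with weak_band entirely below strong_band",
         call. = FALSE)
  }
  if (mz_jitter_sd < 0) stop("mz_jitter_sd must be >= 0", call. = FALSE)
  structure(
    list(strong_band = strong_band, weak_band = weak_band,
         mz_jitter_sd = mz_jitter_sd,
         n_noise_peaks = as.integer(n_noise_peaks),
         noise_max = noise_max, seed = as.integer(seed),
         convention = convention),
    class = "spectrum_sim_config"
  )
}

#' Simulate a high-energy CID spectrum of a permethylated chain
#'
#' Emits every feasible fragment of the chain (see [enumerate_fragments()]):
#' `feasible_strong` ions draw intensities uniformly from the strong band,
#' `feasible_weak` from the weak band; infeasible ions are never emitted.
#' Isobaric ions (e.g. E/G, B/Z) collapse to a single peak carrying the
#' larger intensity. Every real peak's m/z is jittered by N(0, sd^2); noise
#' peaks are added uniformly over the scan range (150 Da to the precursor);
#' intensities are renormalized to base peak 1.
#'
#' @param chain a [glucan_chain()] of DP 2-8.
#' @param config a [spectrum_sim_config()].
#' @return A [peak_list()] whose metadata records the chain notation and
#'   seed; precursor is the permethylated sodiated chain mass.
#' @export
#' @examples
#' cfg <- spectrum_sim_config(mz_jitter_sd = 0, n_noise_peaks = 0, seed = 7)
#' simulate_spectrum(parse_chain("G3G4G3G4G"), cfg)
simulate_spectrum <- function(chain, config) {
  stopifnot(is_glucan_chain(chain), inherits(config, "spectrum_sim_config"))
  if (chain$n_residues < 2L || chain$n_residues > 8L) {
    stop("spectrum simulation supports DP 2..8", call. = FALSE)
  }
  rng <- local_rng(config$seed)
  frags <- enumerate_fragments(chain, config$convention)
  frags <- frags[frags$feasibility != "infeasible", , drop = FALSE]
  lo <- ifelse(frags$feasibility == "feasible_strong",
               config$strong_band[1], config$weak_band[1])
  hi <- ifelse(frags$feasibility == "feasible_strong",
               config$strong_band[2], config$weak_band[2])
  intensity <- lo + rng$unif(nrow(frags)) * (hi - lo)
  # collapse isobars (same nominal position) to the strongest component
  key <- round(frags$mz, 6)
  keep_int <- tapply(intensity, key, max)
  mz <- as.numeric(names(keep_int))
  intensity <- as.numeric(keep_int)
  if (config$mz_jitter_sd > 0) {
    mz <- mz + rng$norm(length(mz), 0, config$mz_jitter_sd)
  }
  precursor <- chain_mass(chain, "permethylated", config$convention, "sodium")
  if (config$n_noise_peaks > 0L) {
    nmz <- 150 + rng$unif(config$n_noise_peaks) * (precursor - 150)
    nint <- rng$unif(config$n_noise_peaks) * config$noise_max
    mz <- c(mz, nmz)
    intensity <- c(intensity, nint)
  }
  peak_list(mz, intensity, precursor_mz = precursor,
            metadata = list(label = to_notation(chain),
                            seed = config$seed,
                            convention = config$convention))
}

#' Reference spectra: all-1,4 and all-1,3 pentaose fixtures
#'
#' Simulates the pair of comparative reference spectra — permethylated
#' cellopentaose (all 1,4) and laminaripentaose (all 1,3) — used to read a
#' test pentasaccharide spectrum. Seeds are pinned (offsets from
#' `config$seed`) so the fixtures regenerate byte-identically; the copies
#' shipped under `inst/extdata/` were written with the default
#' configuration (`seed = 20,` clean: no jitter, no noise) by
#' [write_peaklist()].
#'
#' @param config a [spectrum_sim_config()]; defaults to a clean
#'   configuration with seed 20.
#' @return Named list `all14`, `all13` of [peak_list()].
#' @export
make_reference_fixtures <- function(config = spectrum_sim_config(
                                      mz_jitter_sd = 0, n_noise_peaks = 0,
                                      seed = 20)) {
  stopifnot(inherits(config, "spectrum_sim_config"))
  cfg14 <- config
  cfg14$seed <- config$seed + 1L
  cfg13 <- config
  cfg13$seed <- config$seed + 2L
  list(
    all14 = simulate_spectrum(parse_chain("G4G4G4G4G"), cfg14),
    all13 = simulate_spectrum(parse_chain("G3G3G3G3G"), cfg13)
  )
}
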