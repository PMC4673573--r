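#' Mass constants for glucan mass arithmetic
#'
#' All mass bookkeeping in the package goes through this single table.
#' Monoisotopic values are computed from IUPAC atomic masses
#' (H 1.0078250319, C 12 exactly, O 15.9949146221); average values use
#' standard atomic weights (H 1.00794, C 12.0107, O 15.9994). The sodium
#' adduct constant is fixed at 22.9898 Da (monoisotopic) / 22.99 Da
#' (average); MALDI of permethylated glycans yields singly sodiated ions.
#'
#' @param convention `"monoisotopic"` or `"average"`.
#' @return Named numeric vector of constants (Da): `residue` (anhydroglucose,
#'   C6H10O5), `residue_perme` (permethylated anhydroglucose, C9H16O5),
#'   `water`, `ch2` (methylene increment per methyl group), `h2`
#'   (reduction of the reducing end to the alditol), `proton`, `sodium`,
#'   and the small neutral losses used by the fragment tables (`ch3oh`,
#'   `ch2o`, `c2h4o`, `c3h4o`, `c4h8o2`).
#' @export
#' @examples
#' mass_constants("monoisotopic")[["residue"]]  # 162.0528
mass_constants <- function(convention = c("monoisotopic", "average")) {
  convention <- match.arg(convention)
  if (convention == "monoisotopic") {
    h <- 1.0078250319
    c <- 12
    o <- 15.9949146221
    na <- 22.9898
    pr <- 1.0072765
  } else {
    h <- 1.00794
    c <- 12.0107
    o <- 15.9994
    na <- 22.99
    pr <- 1.00739
  }
  ch2 <- c + 2 * h
  c(
    residue       = 6 * c + 10 * h + 5 * o,
    residue_perme = 9 * c + 16 * h + 5 * o,
    water         = 2 * h + o,
    ch2           = ch2,
    h2            = 2 * h,
    proton        = pr,
    sodium        = na,
    ch3oh         = c + 4 * h + o,
    ch2o          = c + 2 * h + o,
    c2h4o         = 2 * c + 4 * h + o,
    c3h4o         = 3 * c + 4 * h + o,
    c4h8o2        = 4 * c + 8 * h + 2 * o
  )
}

#' Adduct mass
#' @param adduct `"none"`, `"proton"` or `"sodium"`.
#' @param convention mass convention, see [mass_constants()].
#' @return Adduct mass in Da (0 for `"none"`).
#' @export
adduct_mass <- function(adduct = c("none", "proton", "sodium"),
                        convention = c("monoisotopic", "average")) {
  adduct <- match.arg(adduct)
  if (adduct == "none") return(0)
  k <- mass_constants(convention)
  unname(k[[if (adduct == "proton") "proton" else "sodium"]])
}
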