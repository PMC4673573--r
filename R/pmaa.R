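#' PMAA linkage profiles
#'
#' A `linkage_profile` holds the partially-methylated-alditol-acetate
#' (methylation analysis) composition of a reduced linear
#' gluco-oligosaccharide: counts (or t-Glc-normalized molar ratios) of
#' terminal Glc (`t_glc`), 3-O-substituted Glc (`glc3`), 4-O-substituted Glc
#' (`glc4`), and the 3- or 4-O-substituted reducing-end alditol (`glcol3`,
#' `glcol4`). The reducing end is reduced to the alditol before methylation,
#' so it is distinguishable from internal residues.
#'
#' @param t_glc,glc3,glc4,glcol3,glcol4 nonnegative counts or ratios.
#' @param normalized logical: `FALSE` for raw integer counts (must sum to
#'   the DP), `TRUE` for molar ratios expressed relative to t-Glc = 1.00.
#' @return An object of class `linkage_profile`.
#' @export
linkage_profile <- function(t_glc, glc3 = 0, glc4 = 0, glcol3 = 0, glcol4 = 0,
                            normalized = FALSE) {
  v <- c(t_glc = as.numeric(t_glc), glc3 = as.numeric(glc3),
         glc4 = as.numeric(glc4), glcol3 = as.numeric(glcol3),
         glcol4 = as.numeric(glcol4))
  if (anyNA(v) || any(v < 0)) stop("profile entries must be nonnegative",
                                   call. = FALSE)
  if (!normalized && any(abs(v - round(v)) > 1e-9)) {
    stop("raw (non-normalized) profiles must have integer counts", call. = FALSE)
  }
  structure(list(values = v, normalized = isTRUE(normalized)),
            class = "linkage_profile")
}

#' @export
print.linkage_profile <- function(x, ...) {
  cat(sprintf("<linkage_profile>%s\n",
              if (x$normalized) " (ratios, t-Glc = 1.00)" else " (counts)"))
  print(round(x$values, 3))
  invisible(x)
}

#' Normalize a profile to t-Glc = 1.00
#' @param profile a [linkage_profile()].
#' @return A normalized [linkage_profile()].
#' @export
as_ratios <- function(profile) {
  stopifnot(inherits(profile, "linkage_profile"))
  if (profile$normalized) return(profile)
  if (profile$values[["t_glc"]] <= 0) {
    stop("cannot normalize: t_glc is zero", call. = FALSE)
  }
  v <- profile$values / profile$values[["t_glc"]]
  linkage_profile(v[["t_glc"]], v[["glc3"]], v[["glc4"]],
                  v[["glcol3"]], v[["glcol4"]], normalized = TRUE)
}

#' Predict the PMAA profile of a chain
#'
#' Models methylation analysis after borohydride reduction: the nonreducing
#' terminus yields t-Glc, each internal residue yields 3-Glc or 4-Glc
#' according to the linkage it receives, and the reducing terminus yields
#' the 3- or 4-substituted glucitol. DP 1 is rejected (free glucitol is not
#' part of the profile vocabulary).
#'
#' @param chain a [glucan_chain()] of DP >= 2.
#' @return A raw-count [linkage_profile()].
#' @export
#' @examples
#' predict_pmaa(parse_chain("G3G4G3G4G"))
predict_pmaa <- function(chain) {
  stopifnot(is_glucan_chain(chain))
  n <- chain$n_residues
  if (n < 2L) stop("PMAA profile requires DP >= 2", call. = FALSE)
  lv <- chain$linkages
  internal <- if (n > 2L) lv[seq_len(n - 2L)] else integer()
  last <- lv[n - 1L]
  linkage_profile(
    t_glc = 1,
    glc3 = sum(internal == 3L),
    glc4 = sum(internal == 4L),
    glcol3 = as.numeric(last == 3L),
    glcol4 = as.numeric(last == 4L)
  )
}

#' Enumerate candidate structures for a profile
#'
#' Brute-force enumeration of all `2^(dp-1)` linkage vectors of the given
#' DP, filtered to those whose predicted PMAA profile equals the supplied
#' integer profile. Methylation analysis counts linkage types but carries no
#' positional information, so several sequences typically share one profile;
#' the returned candidates are in lexicographic notation order.
#'
#' @param dp integer DP, 2..12.
#' @param profile a raw-count [linkage_profile()] whose counts sum to `dp`.
#' @return List of [glucan_chain()] candidates (possibly empty).
#' @export
#' @examples
#' candidate_structures(5, linkage_profile(1, 2, 1, 0, 1))
candidate_structures <- function(dp, profile) {
  dp <- as.integer(dp)
  if (is.na(dp) || dp < 2L || dp > 12L) {
    stop("dp must be an integer in 2..12", call. = FALSE)
  }
  stopifnot(inherits(profile, "linkage_profile"))
  if (profile$normalized) {
    stop("candidate enumeration needs a raw integer-count profile", call. = FALSE)
  }
  if (sum(profile$values) != dp) {
    stop(sprintf("profile counts sum to %s, inconsistent with dp = %d",
                 format(sum(profile$values)), dp), call. = FALSE)
  }
  nb <- dp - 1L
  grid <- as.matrix(expand.grid(rep(list(c(3L, 4L)), nb)))
  keep <- logical(nrow(grid))
  for (r in seq_len(nrow(grid))) {
    keep[r] <- identical(predict_pmaa(glucan_chain(grid[r, ]))$values,
                         profile$values)
  }
  cands <- lapply(which(keep), function(r) glucan_chain(grid[r, ]))
  cands[order(vapply(cands, to_notation, character(1)))]
}

#' Least-squares distance between an observed and a predicted profile
#'
#' Observed methylation-analysis molar ratios deviate from integers because
#' of recovery and derivatization bias, so candidates are ranked by shape:
#' the sum of squared deviations between the observed t-Glc-normalized
#' ratios and the candidate's integer profile (also normalized to t-Glc =
#' 1). Zero iff the observed ratios are exactly the predicted integers.
#'
#' @param observed a normalized [linkage_profile()] (t-Glc = 1.00).
#' @param chain a [glucan_chain()] candidate.
#' @return Nonnegative score.
#' @export
#' @examples
#' obs <- linkage_profile(1.00, 1.72, 1.14, 0, 0.53, normalized = TRUE)
#' profile_distance(obs, parse_chain("G3G4G3G4G"))  # ~0.319
profile_distance <- function(observed, chain) {
  stopifnot(inherits(observed, "linkage_profile"))
  if (!observed$normalized) observed <- as_ratios(observed)
  pred <- as_ratios(predict_pmaa(chain))
  sum((observed$values - pred$values)^2)
}

#' Rank candidate structures against an observed profile
#'
#' @param observed a normalized [linkage_profile()].
#' @param candidates list of [glucan_chain()].
#' @return data.frame (`notation`, `distance`, `rank`) sorted by distance;
#'   candidates at equal distance share a rank (ties are reported as ties,
#'   not broken arbitrarily).
#' @export
rank_candidates <- function(observed, candidates) {
  stopifnot(length(candidates) >= 1L)
  d <- vapply(candidates, function(ch) profile_distance(observed, ch), numeric(1))
  o <- order(d, vapply(candidates, to_notation, character(1)))
  d <- d[o]
  data.frame(
    notation = vapply(candidates[o], to_notation, character(1)),
    distance = d,
    rank = match(round(d, 12), unique(round(d, 12))),
    stringsAsFactors = FALSE
  )
}

#' Read / write linkage-profile tables
#'
#' TSV layout mirroring a methylation-analysis table: columns `fraction`,
#' `t_glc`, `glc3`, `glc4`, `glcol3`, `glcol4`. Missing ("not detected")
#' entries may be written as `-` and are read as 0.
#'
#' @param path file path.
#' @param normalized whether the stored values are t-Glc-normalized ratios.
#' @return `read_linkage_table` returns a named list of [linkage_profile()];
#'   `write_linkage_table` returns `path` invisibly.
#' @export
read_linkage_table <- function(path, normalized = TRUE) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  needed <- c("fraction", "t_glc", "glc3", "glc4", "glcol3", "glcol4")
  if (!all(needed %in% names(df))) {
    stop("linkage table must have columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  num <- function(x) {
    x[x %in% c("-", "")] <- "0"
    as.numeric(x)
  }
  out <- lapply(seq_len(nrow(df)), function(i) {
    linkage_profile(num(df$t_glc[i]), num(df$glc3[i]), num(df$glc4[i]),
                    num(df$glcol3[i]), num(df$glcol4[i]),
                    normalized = normalized)
  })
  stats::setNames(out, df$fraction)
}

#' @rdname read_linkage_table
#' @param profiles named list of [linkage_profile()].
#' @export
write_linkage_table <- function(profiles, path) {
  rows <- lapply(names(profiles), function(nm) {
    v <- profiles[[nm]]$values
    data.frame(fraction = nm, t_glc = v[["t_glc"]], glc3 = v[["glc3"]],
               glc4 = v[["glc4"]], glcol3 = v[["glcol3"]],
               glcol4 = v[["glcol4"]], stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
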