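#' Linear beta-glucan chains
#'
#' A `glucan_chain` represents a linear chain of beta-D-glucopyranosyl
#' residues joined by 1,3- or 1,4-glucosidic bonds. Residue 1 is the
#' nonreducing terminus and residue `n` the reducing terminus, matching the
#' left-to-right reading of the compact notation (`"G3G4G"` is
#' beta-Glc-1,3-beta-Glc-1,4-Glc). Linkage `i` is the bond donated by the
#' anomeric carbon (C1) of residue `i` to O3 or O4 of residue `i + 1`.
#'
#' Only beta anomeric configuration and 1,3/1,4 linkages are representable;
#' branched glycans (e.g. the 1,6 branches of laminarin) are deliberately
#' not expressible.
#'
#' @param linkages integer vector of 3s and 4s, one element per glucosidic
#'   bond (length 0 for free glucose).
#' @return An object of class `glucan_chain`: a list with `n_residues`
#'   (DP) and `linkages`.
#' @seealso [parse_chain()], [to_notation()], [chain_mass()]
#' @export
#' @examples
#' glucan_chain(c(3, 4, 3, 4))  # G3G4G3G4G
glucan_chain <- function(linkages = integer()) {
  if (length(linkages) == 0) linkages <- integer()
  linkages <- as.integer(linkages)
  if (anyNA(linkages) || !all(linkages %in% c(3L, 4L))) {
    stop("linkages must be a vector of 3s and 4s", call. = FALSE)
  }
  structure(
    list(n_residues = length(linkages) + 1L, linkages = linkages),
    class = "glucan_chain"
  )
}

#' @export
print.glucan_chain <- function(x, ...) {
  cat(sprintf("<glucan_chain> DP %d: %s\n", x$n_residues, to_notation(x)))
  invisible(x)
}

#' @export
format.glucan_chain <- function(x, ...) to_notation(x)

#' @export
`==.glucan_chain` <- function(e1, e2) {
  identical(e1$linkages, e2$linkages)
}

#' Test for glucan_chain
#' @param x object.
#' @return `TRUE` if `x` is a [glucan_chain()].
#' @export
is_glucan_chain <- function(x) inherits(x, "glucan_chain")

#' Parse compact glucan notation
#'
#' Parses strings of the grammar `G((3|4)G)*`, read nonreducing to reducing:
#' `"G3G4G3G4G"` is the pentasaccharide with linkages 3,4,3,4 and `"G"` is
#' free glucose. Malformed input raises an error naming the first offending
#' character position.
#'
#' @param notation character scalar in compact notation.
#' @return A [glucan_chain()].
#' @export
#' @examples
#' parse_chain("G3G4G3G4G")
#' parse_chain("G")$n_residues
parse_chain <- function(notation) {
  if (!is.character(notation) || length(notation) != 1L || is.na(notation)) {
    stop("notation must be a single character string", call. = FALSE)
  }
  ch <- strsplit(notation, "", fixed = TRUE)[[1]]
  if (length(ch) == 0L) {
    stop("parse error at position 1: empty notation", call. = FALSE)
  }
  # positions 1,3,5,... must be 'G'; positions 2,4,... must be '3' or '4'
  for (i in seq_along(ch)) {
    if (i %% 2L == 1L) {
      if (ch[i] != "G") {
        stop(sprintf("parse error at position %d: expected 'G', got '%s'",
                     i, ch[i]), call. = FALSE)
      }
    } else {
      if (!ch[i] %in% c("3", "4")) {
        stop(sprintf("parse error at position %d: expected '3' or '4', got '%s'",
                     i, ch[i]), call. = FALSE)
      }
    }
  }
  if (length(ch) %% 2L == 0L) {
    stop(sprintf("parse error at position %d: trailing linkage digit",
                 length(ch)), call. = FALSE)
  }
  if (length(ch) == 1L) return(glucan_chain())
  glucan_chain(as.integer(ch[seq(2L, length(ch) - 1L, by = 2L)]))
}

#' Serialize a chain to compact notation
#'
#' Inverse of [parse_chain()]: `parse_chain(to_notation(x))` is the identity
#' for every valid chain.
#'
#' @param chain a [glucan_chain()].
#' @return Character scalar, e.g. `"G3G"` for laminaribiose.
#' @export
to_notation <- function(chain) {
  stopifnot(is_glucan_chain(chain))
  if (chain$n_residues == 1L) return("G")
  paste0("G", paste0(chain$linkages, "G", collapse = ""))
}

#' Mass of a (derivatized) glucan chain
#'
#' Native chain mass is `n * residue + water`. Permethylation adds one
#' methylene equivalent per free hydroxyl; a linear chain of DP `n` carries
#' `3n + 2` free hydroxyls (nonreducing terminus 4, each internal residue 3,
#' reducing terminus 4), or `3n + 3` after borohydride reduction to the
#' alditol (open-chain reducing residue gains one hydroxyl). Reduction also
#' adds H2.
#'
#' @param chain a [glucan_chain()].
#' @param derivatization one of `"native"`, `"reduced"`, `"permethylated"`,
#'   `"permethylated_reduced"`.
#' @param convention `"monoisotopic"` or `"average"`.
#' @param adduct `"none"` (neutral mass), `"proton"`, or `"sodium"`.
#' @return Mass (or singly charged m/z when an adduct is given) in Da.
#' @export
#' @examples
#' cello5 <- parse_chain("G4G4G4G4G")
#' chain_mass(cello5)                                        # 828.27
#' chain_mass(cello5, "permethylated", adduct = "sodium")    # 1089.53
chain_mass <- function(chain,
                       derivatization = c("native", "reduced",
                                          "permethylated",
                                          "permethylated_reduced"),
                       convention = c("monoisotopic", "average"),
                       adduct = c("none", "proton", "sodium")) {
  stopifnot(is_glucan_chain(chain))
  derivatization <- match.arg(derivatization)
  convention <- match.arg(convention)
  adduct <- match.arg(adduct)
  k <- mass_constants(convention)
  n <- chain$n_residues
  m <- n * k[["residue"]] + k[["water"]]
  if (derivatization %in% c("reduced", "permethylated_reduced")) {
    m <- m + k[["h2"]]
  }
  if (derivatization == "permethylated") {
    m <- m + (3 * n + 2) * k[["ch2"]]
  } else if (derivatization == "permethylated_reduced") {
    m <- m + (3 * n + 3) * k[["ch2"]]
  }
  unname(m + adduct_mass(adduct, convention))
}

#' Count free hydroxyls by explicit per-residue bookkeeping
#'
#' Slow reference implementation used to validate the closed form
#' `3n + 2` in [chain_mass()]: walks the chain residue by residue and counts
#' the hydroxyls each one retains after accounting for the glycosidic bonds
#' it donates and receives.
#'
#' @param chain a [glucan_chain()].
#' @param reduced logical; count for the borohydride-reduced (alditol) chain.
#' @return Integer hydroxyl count.
#' @export
count_free_hydroxyls <- function(chain, reduced = FALSE) {
  stopifnot(is_glucan_chain(chain))
  n <- chain$n_residues
  total <- 0L
  for (i in seq_len(n)) {
    # ring glucose hydroxyl positions: 1 (anomeric), 2, 3, 4, 6;
    # open-chain glucitol: 1, 2, 3, 4, 5, 6
    oh <- if (reduced && i == n) c(1L, 2L, 3L, 4L, 5L, 6L) else c(1L, 2L, 3L, 4L, 6L)
    if (i < n) oh <- setdiff(oh, 1L)                      # donates C1
    if (i > 1L) oh <- setdiff(oh, chain$linkages[i - 1L]) # receives at O3/O4
    total <- total + length(oh)
  }
  total
}

#' Read chains from a plain-text notation file
#'
#' One compact-notation chain per line; blank lines and `#` comments are
#' skipped. A FASTA-like variant with `>id` header lines is also accepted,
#' in which case the returned list is named by the ids.
#'
#' @param path file path.
#' @return List of [glucan_chain()] objects.
#' @export
read_chains <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) return(list())
  if (any(startsWith(lines, ">"))) {
    hdr <- startsWith(lines, ">")
    if (!hdr[1] || any(diff(which(hdr)) < 2)) {
      stop("malformed FASTA-like chain file: every '>' header needs one chain line",
           call. = FALSE)
    }
    ids <- sub("^>\\s*", "", lines[hdr])
    chains <- lapply(lines[!hdr], parse_chain)
    names(chains) <- ids
    return(chains)
  }
  lapply(lines, parse_chain)
}

#' Write chains to a plain-text notation file
#'
#' @param chains list of [glucan_chain()] (names, if present, are written as
#'   `>id` headers).
#' @param path file path.
#' @param header optional comment line(s) written at the top (prefixed `#`).
#' @return `path`, invisibly.
#' @export
write_chains <- function(chains, path, header = NULL) {
  if (is_glucan_chain(chains)) chains <- list(chains)
  out <- character()
  if (!is.null(header)) out <- paste0("# ", header)
  nm <- names(chains)
  for (i in seq_along(chains)) {
    if (!is.null(nm) && nzchar(nm[i])) out <- c(out, paste0(">", nm[i]))
    out <- c(out, to_notation(chains[[i]]))
  }
  writeLines(out, path)
  invisible(path)
}
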