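#' Subsite rule sets for glycoside hydrolases
#'
#' An `enzyme_ruleset` declares, in subsite terms, which glucosidic bonds an
#' endo-glucanase hydrolyzes. The scissile bond sits between subsites -1 and
#' +1; the residue on the nonreducing side of -1 occupies -2 and the residue
#' beyond +1 occupies +2. A bond is cleavable when every clause holds:
#'
#' * its linkage type is in `cleavable_linkages`;
#' * the substrate DP is at least `min_substrate_dp`;
#' * the linkage between subsites -2 and -1 (i.e. the bond on the
#'   nonreducing side of the scissile bond) matches
#'   `required_linkage_minus2_minus1` (`"L3"`, `"L4"`, `"any"`, or
#'   `"must_be_chain_end"`, which demands that -1 is the nonreducing
#'   terminus). When `required_occupancy_minus2` is `TRUE`, an empty -2
#'   subsite never licenses cleavage;
#' * the linkage between +1 and +2 matches `required_linkage_plus1_plus2`
#'   (`"L3"`, `"L4"`, `"any"`); if +2 is empty (the scissile bond is the
#'   last bond of the chain) the clause holds only when `plus2_may_be_empty`.
#'
#' @param name identifier.
#' @param cleavable_linkages nonempty subset of `c(3, 4)`.
#' @param required_linkage_minus2_minus1 `"L3"`, `"L4"`, `"any"` or
#'   `"must_be_chain_end"`.
#' @param required_occupancy_minus2 logical.
#' @param required_linkage_plus1_plus2 `"L3"`, `"L4"` or `"any"`.
#' @param plus2_may_be_empty logical.
#' @param min_substrate_dp integer >= 2.
#' @return An object of class `enzyme_ruleset`.
#' @seealso [shipped_rulesets()], [cleavable_bonds()], [limit_digest()]
#' @export
enzyme_ruleset <- function(name,
                           cleavable_linkages,
                           required_linkage_minus2_minus1 = "any",
                           required_occupancy_minus2 = FALSE,
                           required_linkage_plus1_plus2 = "any",
                           plus2_may_be_empty = TRUE,
                           min_substrate_dp = 2L) {
  cleavable_linkages <- sort(unique(as.integer(cleavable_linkages)))
  if (length(cleavable_linkages) == 0L ||
      !all(cleavable_linkages %in% c(3L, 4L))) {
    stop("cleavable_linkages must be a nonempty subset of c(3, 4)", call. = FALSE)
  }
  required_linkage_minus2_minus1 <- match.arg(
    required_linkage_minus2_minus1, c("L3", "L4", "any", "must_be_chain_end"))
  required_linkage_plus1_plus2 <- match.arg(
    required_linkage_plus1_plus2, c("L3", "L4", "any"))
  min_substrate_dp <- as.integer(min_substrate_dp)
  if (is.na(min_substrate_dp) || min_substrate_dp < 2L) {
    stop("min_substrate_dp must be an integer >= 2", call. = FALSE)
  }
  structure(
    list(
      name = as.character(name),
      cleavable_linkages = cleavable_linkages,
      required_linkage_minus2_minus1 = required_linkage_minus2_minus1,
      required_occupancy_minus2 = isTRUE(required_occupancy_minus2),
      required_linkage_plus1_plus2 = required_linkage_plus1_plus2,
      plus2_may_be_empty = isTRUE(plus2_may_be_empty),
      min_substrate_dp = min_substrate_dp
    ),
    class = "enzyme_ruleset"
  )
}

#' @export
print.enzyme_ruleset <- function(x, ...) {
  cat(sprintf(
    "<enzyme_ruleset> %s: cleaves L%s; -2/-1 %s%s; +1/+2 %s%s; min DP %d\n",
    x$name, paste(x$cleavable_linkages, collapse = "/L"),
    x$required_linkage_minus2_minus1,
    if (x$required_occupancy_minus2) " (-2 occupied)" else "",
    x$required_linkage_plus1_plus2,
    if (x$plus2_may_be_empty) " (+2 may be empty)" else "",
    x$min_substrate_dp))
  invisible(x)
}

#' Test for enzyme_ruleset
#' @param x object.
#' @return `TRUE` if `x` is an [enzyme_ruleset()].
#' @export
is_enzyme_ruleset <- function(x) inherits(x, "enzyme_ruleset")

#' Shipped enzyme rule sets
#'
#' Rule sets for the four enzymes relevant to MLG fine-structure work,
#' reverse-engineered from their documented limit-digest products on
#' barley-type beta-1,3:1,4-glucan:
#'
#' * `GH12_aniger` — *Aspergillus niger* endo-beta-1,4-glucanase: cleaves a
#'   1,4 bond only when preceded (nonreducing side) by another 1,4 bond and
#'   followed by a 1,3 bond; min DP 4. On canonical MLG this releases G3G4G
#'   from cellotriosyl and G3G4G4G from cellotetraosyl units and leaves both
#'   products (and G3G4G3G4G) intact.
#' * `GH16_trichoderma` — *Trichoderma* sp. endo-beta-1,3(4)-glucanase:
#'   cleaves 1,3 or 1,4 bonds when the -2/-1 linkage is 1,3 and the +1/+2
#'   linkage is 1,3 (or +2 is empty); min DP 4, i.e. its smallest MLG
#'   substrate is G3G4G3G. Converts G3G4G3G4G to two laminaribiose plus
#'   glucose, leaves G3G4G4G and G3G4G intact, degrades all-1,3 chains, and
#'   is inert on all-1,4 chains. Whether the enzyme also attacks 1,3 bonds
#'   in MLG context cannot be decided from limit-digest products alone (both
#'   bonds it cleaves in G3G4G3G4G are 1,4); the rule set permits both.
#' * `GH17_barley` — barley endo-beta-1,3-glucanase (GI/GII): cleaves a 1,3
#'   bond only after another 1,3 bond (laminaritriose is the smallest
#'   substrate); min DP 3. Inert on MLG, which lacks consecutive 1,3 bonds.
#' * `GH_lichenase` — EC 3.2.1.73 endo-beta-1,3:1,4-glucanase: cleaves the
#'   1,4 bond following a 1,3 bond, giving the classical G4G3G-type
#'   products.
#'
#' @param name one of `"GH12_aniger"`, `"GH16_trichoderma"`, `"GH17_barley"`,
#'   `"GH_lichenase"`; `NULL` returns the full named list.
#' @return An [enzyme_ruleset()] or a named list of them.
#' @export
#' @examples
#' shipped_rulesets("GH16_trichoderma")
shipped_rulesets <- function(name = NULL) {
  sets <- list(
    GH12_aniger = enzyme_ruleset(
      "GH12_aniger", cleavable_linkages = 4L,
      required_linkage_minus2_minus1 = "L4", required_occupancy_minus2 = TRUE,
      required_linkage_plus1_plus2 = "L3", plus2_may_be_empty = FALSE,
      min_substrate_dp = 4L),
    GH16_trichoderma = enzyme_ruleset(
      "GH16_trichoderma", cleavable_linkages = c(3L, 4L),
      required_linkage_minus2_minus1 = "L3", required_occupancy_minus2 = TRUE,
      required_linkage_plus1_plus2 = "L3", plus2_may_be_empty = TRUE,
      min_substrate_dp = 4L),
    GH17_barley = enzyme_ruleset(
      "GH17_barley", cleavable_linkages = 3L,
      required_linkage_minus2_minus1 = "L3", required_occupancy_minus2 = TRUE,
      required_linkage_plus1_plus2 = "any", plus2_may_be_empty = TRUE,
      min_substrate_dp = 3L),
    GH_lichenase = enzyme_ruleset(
      "GH_lichenase", cleavable_linkages = 4L,
      required_linkage_minus2_minus1 = "L3", required_occupancy_minus2 = TRUE,
      required_linkage_plus1_plus2 = "any", plus2_may_be_empty = TRUE,
      min_substrate_dp = 3L)
  )
  if (is.null(name)) return(sets)
  if (!name %in% names(sets)) {
    stop(sprintf("unknown rule set '%s'; shipped: %s",
                 name, paste(names(sets), collapse = ", ")), call. = FALSE)
  }
  sets[[name]]
}

#' Read / write enzyme rule sets as JSON
#'
#' The JSON schema mirrors the [enzyme_ruleset()] fields verbatim.
#'
#' @param path file path.
#' @return `read_ruleset` returns an [enzyme_ruleset()]; `write_ruleset`
#'   returns `path` invisibly.
#' @export
read_ruleset <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  needed <- c("name", "cleavable_linkages", "required_linkage_minus2_minus1",
              "required_occupancy_minus2", "required_linkage_plus1_plus2",
              "plus2_may_be_empty", "min_substrate_dp")
  missing <- setdiff(needed, names(j))
  if (length(missing)) {
    stop("rule-set JSON missing fields: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  enzyme_ruleset(
    name = j$name,
    cleavable_linkages = j$cleavable_linkages,
    required_linkage_minus2_minus1 = j$required_linkage_minus2_minus1,
    required_occupancy_minus2 = j$required_occupancy_minus2,
    required_linkage_plus1_plus2 = j$required_linkage_plus1_plus2,
    plus2_may_be_empty = j$plus2_may_be_empty,
    min_substrate_dp = j$min_substrate_dp
  )
}

#' @rdname read_ruleset
#' @param rules an [enzyme_ruleset()].
#' @export
write_ruleset <- function(rules, path) {
  stopifnot(is_enzyme_ruleset(rules))
  jsonlite::write_json(unclass(rules), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
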