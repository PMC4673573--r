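#' Peak lists
#'
#' A `peak_list` is a centroided spectrum: (m/z, relative intensity) pairs
#' with intensities normalized to base peak = 1 and peaks sorted by m/z,
#' plus an optional precursor m/z and free-form metadata (label, seed,
#' tolerance, ...).
#'
#' @param mz numeric vector of m/z values (> 0).
#' @param intensity numeric vector of intensities (>= 0; renormalized to
#'   base peak = 1).
#' @param precursor_mz optional precursor m/z.
#' @param metadata named list.
#' @return An object of class `peak_list` with elements `peaks` (data.frame
#'   `mz`, `intensity`), `precursor_mz`, `metadata`.
#' @export
peak_list <- function(mz, intensity, precursor_mz = NA_real_,
                      metadata = list()) {
  stopifnot(length(mz) == length(intensity))
  if (length(mz) > 0) {
    if (any(mz <= 0) || any(intensity < 0)) {
      stop("peaks need mz > 0 and intensity >= 0", call. = FALSE)
    }
    o <- order(mz)
    mz <- mz[o]
    intensity <- intensity[o]
    if (max(intensity) > 0) intensity <- intensity / max(intensity)
  }
  structure(
    list(peaks = data.frame(mz = as.numeric(mz),
                            intensity = as.numeric(intensity)),
         precursor_mz = precursor_mz,
         metadata = metadata),
    class = "peak_list"
  )
}

#' @export
print.peak_list <- function(x, ...) {
  lab <- x$metadata$label
  cat(sprintf("<peak_list>%s %d peak(s)%s\n",
              if (!is.null(lab)) paste0(" '", lab, "'") else "",
              nrow(x$peaks),
              if (!is.na(x$precursor_mz)) sprintf(", precursor m/z %.2f",
                                                  x$precursor_mz) else ""))
  invisible(x)
}

#' Test for peak_list
#' @param x object.
#' @return `TRUE` if `x` is a [peak_list()].
#' @export
is_peak_list <- function(x) inherits(x, "peak_list")

#' Read / write peak lists as two-column TSV
#'
#' Format: optional `#`-prefixed header comments (a
#' `# precursor_mz: <value>` comment, if present, is parsed back), then a
#' header line `mz<TAB>intensity` and one peak per line.
#'
#' @param path file path.
#' @return `read_peaklist` returns a [peak_list()]; `write_peaklist` returns
#'   `path` invisibly.
#' @export
read_peaklist <- function(path) {
  lines <- readLines(path, warn = FALSE)
  com <- lines[startsWith(lines, "#")]
  prec <- NA_real_
  meta <- list()
  for (cl in com) {
    kv <- regmatches(cl, regexec("^#\\s*([A-Za-z_]+):\\s*(.+)$", cl))[[1]]
    if (length(kv) == 3) {
      if (kv[2] == "precursor_mz") prec <- as.numeric(kv[3])
      else meta[[kv[2]]] <- kv[3]
    }
  }
  df <- utils::read.delim(text = paste(lines[!startsWith(lines, "#")],
                                       collapse = "\n"),
                          stringsAsFactors = FALSE)
  if (!all(c("mz", "intensity") %in% names(df))) {
    stop("peak-list TSV needs 'mz' and 'intensity' columns", call. = FALSE)
  }
  peak_list(df$mz, df$intensity, precursor_mz = prec, metadata = meta)
}

#' @rdname read_peaklist
#' @param peaks a [peak_list()].
#' @param digits decimal places written (fixed-width, so files regenerate
#'   byte-identically under a fixed seed).
#' @export
write_peaklist <- function(peaks, path, digits = 4) {
  stopifnot(is_peak_list(peaks))
  hdr <- character()
  for (key in names(peaks$metadata)) {
    hdr <- c(hdr, sprintf("# %s: %s", key, peaks$metadata[[key]]))
  }
  if (!is.na(peaks$precursor_mz)) {
    hdr <- c(hdr, sprintf("# precursor_mz: %.*f", digits, peaks$precursor_mz))
  }
  body <- c("mz\tintensity",
            sprintf(paste0("%.", digits, "f\t%.", digits, "f"),
                    peaks$peaks$mz, peaks$peaks$intensity))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read / write MGF-style peak lists
#'
#' Minimal MGF support: `BEGIN IONS` / `TITLE=` / `PEPMASS=` / one
#' `mz intensity` pair per line / `END IONS`. Only the first block is read.
#'
#' @param path file path.
#' @return `read_mgf` returns a [peak_list()]; `write_mgf` returns `path`
#'   invisibly.
#' @export
read_mgf <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  b <- which(lines == "BEGIN IONS")
  e <- which(lines == "END IONS")
  if (length(b) == 0 || length(e) == 0 || e[1] < b[1]) {
    stop("no BEGIN IONS / END IONS block found", call. = FALSE)
  }
  block <- lines[(b[1] + 1):(e[1] - 1)]
  prec <- NA_real_
  meta <- list()
  peaks <- block[!grepl("=", block, fixed = TRUE)]
  for (kv in block[grepl("=", block, fixed = TRUE)]) {
    parts <- strsplit(kv, "=", fixed = TRUE)[[1]]
    if (parts[1] == "PEPMASS") prec <- as.numeric(strsplit(parts[2], "\\s+")[[1]][1])
    else meta[[tolower(parts[1])]] <- parts[2]
  }
  peaks <- peaks[nzchar(peaks)]
  mat <- do.call(rbind, lapply(strsplit(peaks, "\\s+"), as.numeric))
  if (is.null(mat)) mat <- matrix(numeric(), ncol = 2)
  peak_list(mat[, 1], mat[, 2], precursor_mz = prec, metadata = meta)
}

#' @rdname read_mgf
#' @param peaks a [peak_list()].
#' @export
write_mgf <- function(peaks, path) {
  stopifnot(is_peak_list(peaks))
  out <- "BEGIN IONS"
  if (!is.null(peaks$metadata$label)) {
    out <- c(out, paste0("TITLE=", peaks$metadata$label))
  }
  if (!is.na(peaks$precursor_mz)) {
    out <- c(out, sprintf("PEPMASS=%.4f", peaks$precursor_mz))
  }
  out <- c(out, sprintf("%.4f %.4f", peaks$peaks$mz, peaks$peaks$intensity),
           "END IONS")
  writeLines(out, path)
  invisible(path)
}

#' Annotate a peak list against a chain's theoretical fragments
#'
#' Greedy nearest-match assignment: peak/ion pairs are considered in order
#' of increasing |m/z error| and accepted when both the peak and the ion are
#' still unassigned and the error is within `tolerance`; exact ties are
#' broken toward the lower-m/z ion. Each peak receives at most one ion.
#'
#' @param peaks a [peak_list()].
#' @param chain a [glucan_chain()].
#' @param tolerance match window in Da (default 0.5; use 1.0 when comparing
#'   across mass conventions).
#' @param convention `"monoisotopic"` or `"average"`.
#' @return data.frame with one row per peak: `mz`, `intensity`, `series`,
#'   `index`, `ion`, `theoretical_mz`, `delta` (NA for unassigned peaks).
#' @export
annotate_spectrum <- function(peaks, chain, tolerance = 0.5,
                              convention = c("monoisotopic", "average")) {
  stopifnot(is_peak_list(peaks), tolerance > 0)
  convention <- match.arg(convention)
  np <- nrow(peaks$peaks)
  out <- data.frame(mz = peaks$peaks$mz, intensity = peaks$peaks$intensity,
                    series = rep(NA_character_, np),
                    index = rep(NA_integer_, np),
                    ion = rep(NA_character_, np),
                    theoretical_mz = rep(NA_real_, np),
                    delta = rep(NA_real_, np), stringsAsFactors = FALSE)
  if (np == 0L) return(out)
  ions <- enumerate_fragments(chain, convention)
  ions <- ions[ions$feasibility != "infeasible", , drop = FALSE]
  cand <- expand.grid(p = seq_len(np), f = seq_len(nrow(ions)))
  cand$delta <- peaks$peaks$mz[cand$p] - ions$mz[cand$f]
  cand <- cand[abs(cand$delta) <= tolerance, , drop = FALSE]
  cand <- cand[order(abs(cand$delta), ions$mz[cand$f]), , drop = FALSE]
  p_used <- logical(np)
  f_used <- logical(nrow(ions))
  for (r in seq_len(nrow(cand))) {
    p <- cand$p[r]; f <- cand$f[r]
    if (p_used[p] || f_used[f]) next
    p_used[p] <- TRUE
    f_used[f] <- TRUE
    out$series[p] <- ions$series[f]
    out$index[p] <- ions$index[f]
    out$ion[p] <- ions$ion[f]
    out$theoretical_mz[p] <- ions$mz[f]
    out$delta[p] <- cand$delta[r]
  }
  out
}
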