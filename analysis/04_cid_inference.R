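#!/usr/bin/env Rscript
# Stage 4 — high-energy CID of the permethylated DP-5 species and
# comparative diagnostic-ion inference.
#
# Simulates the spectrum of the (sodiated, permethylated) DP-5 minor
# oligosaccharide alongside the all-1,4 / all-1,3 pentaose references,
# annotates it, and calls each linkage from the 3,5A / V / D diagnostics and
# the D1-vs-E1/G1 intensity comparison.

suppressPackageStartupMessages(library(mlglucan))

seed <- 2026
out_dir <- "results/analysis"
dp5_file <- file.path(out_dir, "dp5_species.txt")
if (!file.exists(dp5_file)) {
  stop("run analysis/02_fractionation_digest.R first", call. = FALSE)
}
dp5_chain <- parse_chain(readLines(dp5_file)[1])

sim <- spectrum_sim_config(mz_jitter_sd = 0.05, n_noise_peaks = 5L,
                           seed = seed + 1L)
spectrum <- simulate_spectrum(dp5_chain, sim)
write_peaklist(spectrum, file.path(out_dir, "dp5_cid_spectrum.tsv"))
refs <- make_reference_fixtures(sim)
write_peaklist(refs$all14, file.path(out_dir, "ref_cellopentaose.tsv"))
write_peaklist(refs$all13, file.path(out_dir, "ref_laminaripentaose.tsv"))

annotation <- annotate_spectrum(spectrum, dp5_chain)
utils::write.table(annotation, file.path(out_dir, "dp5_annotation.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

pmaa <- predict_pmaa(dp5_chain)
inference <- infer_structure(spectrum, dp = 5L, references = refs,
                             profile = pmaa)
writeLines(evidence_report(inference),
           file.path(out_dir, "evidence_report.txt"))
writeLines(if (inference$ambiguous) inference$co_optimal
           else to_notation(inference$chain),
           file.path(out_dir, "called_structure.txt"))

cat(sprintf("precursor [M+Na]+ of the permethylated DP-5 species: %.2f\n",
            spectrum$precursor_mz))
cat("evidence:\n")
cat(paste(" ", evidence_report(inference)), sep = "\n")
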