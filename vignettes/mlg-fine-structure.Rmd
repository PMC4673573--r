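---
title: "Models and methods: MLG fine structure in silico"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: MLG fine structure in silico}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlglucan)
```

This vignette is the package's own account of the science it implements:
the data model, the enzyme model, the fragment chemistry, the inference
procedure, the synthetic-data generator, and the choices made wherever the
design was genuinely open. Everything quantitative stated here is computed
by the package's tests or scripts; nothing is quoted from elsewhere.

## Chains, notation, masses

A chain is a vector of 1,3/1,4 linkage codes read nonreducing→reducing;
`"G3G4G3G4G"` is β-Glc-1,3-β-Glc-1,4-β-Glc-1,3-β-Glc-1,4-Glc. This is the
only representable chemistry: branching (e.g. the 1,6 branches of
laminarin from brown algae) and non-glucose residues are deliberately
unrepresentable, which turns several "the enzyme cannot encounter this"
arguments into type-level guarantees.

Mass arithmetic is centralized in `mass_constants()`. A native chain of DP
$n$ weighs $n \cdot 162.0528 + 18.0106$ Da (monoisotopic); permethylation
adds one 14.0157 Da methylene per free hydroxyl, of which a linear chain
has $3n + 2$ ($3n + 3$ after borohydride reduction opens the reducing end).
The closed form is validated in the tests against a slow per-residue
hydroxyl count (`count_free_hydroxyls()`). Both monoisotopic and average
conventions are carried everywhere because printed m/z values in the
glycomics literature freely mix nominal, monoisotopic and average
calibrations; the fragment tolerance policy below absorbs the difference.

## Enzymes as subsite rule sets

An endo-glucanase is modeled as a declarative constraint set over the four
subsites around the scissile bond (−2, −1, +1, +2): which linkage types it
can hydrolyze, what the −2/−1 and +1/+2 linkages must be, whether an empty
subsite is acceptable, and a minimum substrate DP. This is deliberately a
*limit-digest specificity* model: no kinetics, no binding energies, no time
courses (a `max_rounds` cap gives qualitative partial-digest snapshots).

The shipped rule sets are reverse-engineered from the documented product
patterns of the corresponding enzymes on barley-type MLG, and every clause
is traceable to an observation the test suite checks:

| rule set | cleaves | −2/−1 | +1/+2 | min DP | reproduces |
|---|---|---|---|---|---|
| `GH12_aniger` | 1,4 | 1,4 (occupied) | 1,3 (+2 required) | 4 | MLG → G3G4G + G3G4G4G; all limit products resistant |
| `GH16_trichoderma` | 1,3 & 1,4 | 1,3 (occupied) | 1,3 or +2 empty | 4 | G3G4G3G4G → 2×G3G + G; G3G4G4G and G3G4G resistant; all-1,3 digested; all-1,4 resistant |
| `GH17_barley` | 1,3 | 1,3 (occupied) | any | 3 | laminaritriose smallest substrate; MLG (no consecutive 1,3) untouched |
| `GH_lichenase` | 1,4 | 1,3 (occupied) | any | 3 | classical G4G3G / G4G4G3G products |

Two modeling points deserve emphasis. First, the GH16 rule set permits
cleavage of both 1,3 and 1,4 bonds: both bonds it demonstrably cleaves in
G3G4G3G4G are 1,4, and limit-digest products alone cannot decide whether
1,3 bonds in MLG context would also be attacked, so the permissive choice
is made and flagged here. Second, an empty −2 subsite never licenses
cleavage in any shipped rule set (the `must_be_chain_end` option exists for
exo-acting hypotheticals but is unused).

**Digestion semantics.** `limit_digest()` runs simultaneous mark-and-cleave
rounds: every currently cleavable bond across all current products is cut
in one round, until no product has a cleavable bond. This is deterministic
and independent of any enzyme-visit order. The seeded `sequential_digest()`
(one random cut per step) exists because the order *can* matter: on
G3G4G3G4G under GH16, cutting bond 4 first yields G3G4G3G + Glc and then
two laminaribiose + Glc, while cutting bond 2 first yields laminaribiose +
G3G4G and stalls, G3G4G being below the DP-4 minimum substrate. Both routes
are real interpretations of the product ladder; the package makes no
default claim about which the enzyme takes, and the route-free simultaneous
schedule — which reaches the full limit set — is the default everywhere.

Invariants enforced by tests: residue conservation across every digest,
idempotence of limit digestion on its own products, `cleavage_events ==
molecules_out − molecules_in` (each product molecule carries exactly one
reducing end), and monotonicity (relaxing any clause never shrinks the
cleavable-bond set).

## Methylation analysis (PMAA)

`predict_pmaa()` models methylation-after-reduction exactly: the
nonreducing terminus yields t-Glc, internal residue $i$ yields 3-Glc or
4-Glc according to the linkage it receives, and the reduced reducing end
yields 3-Glcol or 4-Glcol. Observed molar ratios deviate from these
integers through recovery and derivatization bias (the shipped observed
table has 4-Glcol entries from 0.53 to 1.46 where theory says 1.00), so
`rank_candidates()` compares *shapes* by least squares against the
t-Glc-normalized integer profile rather than requiring exact matches, and
reports equal-distance candidates as explicit ties. No bias-correction
model is attempted: the data offer nothing to fit one to.

The key structural fact the enumeration exposes: a PMAA profile constrains
only the multiset of internal linkage types, so a DP-5 profile with two
3-Glc and one 4-Glc admits exactly $\binom{3}{1} = 3$ structures
(G3G3G4G4G, G3G4G3G4G, G4G3G3G4G). Methylation analysis alone cannot order
the linkages; that is the job of the fragment spectra.

## CID fragment chemistry

Fragments of permethylated, sodiated, singly charged linear glucans are
computed from composition tables, never calibrated to observed peaks. With
$R = 204.0998$ Da (permethylated anhydroglucose, monoisotopic):

* glycosidic ions: $B_i = iR + \mathrm{CH_2} + \mathrm{Na}$,
  $C_i = B_i + \mathrm{H_2O}$, and the reducing-side mirror images $Y$, $Z$;
* $^{3,5}A_i = (i{-}1)R + \mathrm{CH_2} + \mathrm{C_4H_8O_2} + \mathrm{Na}$:
  cross-ring cleavage of ring $i$ across C3–C4 and C5–O5, retaining the
  C4–C5–C6 portion. The ion requires ring $i$ to be glycosylated at O4, so
  its presence reads linkage $i-1$ as 1,4 and its absence as 1,3;
* $^{0,2}X_i = Y_i + \mathrm{C_3H_4O}$: linkage-independent, useful as a
  same-region presence control;
* elimination ions: $D_i = C_i - \mathrm{CH_3OH}$ (loss of the O3 methoxyl
  of residue $i$; for $i > 1$ it exists only when linkage $i-1$ is 1,4),
  $E_i = G_i = B_i - \mathrm{CH_2O}$ (isobaric, exactly one oxygen — 15.995
  Da — below $D_i$), and $V_i = Z_i - \mathrm{C_2H_4O}$, indexed from the
  reducing end and diagnostic of linkage $\mathrm{DP} - i$.

The index conventions are data, not code: for DP 5, V₄↔linkage 1,
V₃↔linkage 2, V₂↔linkage 3, ³,⁵Aᵢ↔linkage i−1, D₁/E₁/G₁↔linkage 1,
D₄↔linkage 3. The rule $V_i \leftrightarrow$ linkage $(\mathrm{DP} - i)$ is
applied to other DPs as an extrapolation and said so here: the comparative
evidence behind it is pentasaccharide evidence.

The exact elemental compositions of the D/E/G/V elimination ions for
permethylated sodiated glucans are not uniquely fixed by the internal
spacing constraints plus the handful of printed anchor values available for
pentasaccharides; the neutral-loss assignments above were chosen as the
chemically simplest set consistent with all of them. Three guards keep this
honest: (i) the calculator takes no anchor as input, so every anchor
comparison in the tests is leave-one-out by construction; (ii) the
exact-spacing invariant (consecutive same-series indices differ by exactly
$R$ in both conventions) is tested for every series; (iii) an explicitly
exploratory `fragment_mz_anchored()` mode (one anchor + spacing) exists for
uncalibrated spectra and is excluded from all validation paths.

**Tolerance policy.** Matching defaults to ±0.5 Da; comparisons against
printed literature-style values use ±1.0 Da because printed glycan CID
series mix nominal, monoisotopic and average calibrations (the package's
own monoisotopic predictions sit within ±0.25 Da of all eleven
pentasaccharide anchor values it is tested against). Only sodiated, singly
charged, permethylated species are modeled; no isotope envelopes.

**Feasibility model.** `enumerate_fragments()` assigns each ion
`feasible_strong`, `feasible_weak` or `infeasible` from the linkage rules
above. D₁ vs E₁/G₁ encodes the comparative intensity observation at the
nonreducing terminus (D₁ enhanced when linkage 1 is 1,3, E₁/G₁ enhanced
when 1,4); V ions of a 1,3 linkage are weak except at the
nonreducing-terminal position, where they vanish. B/Y (strong) and C/Z/⁰,²X
(weak) carry no linkage information and intensity beyond presence is not
modeled for them.

## Inference

`infer_structure()` scores all $2^{\mathrm{DP}-1}$ candidate vectors (or
the PMAA-consistent subset in joint mode). Observations are classified as
absent (< 1% of base peak), weak (1–10%) or strong (≥ 30%) — intensities
between 10% and 30% classify weak with a borderline flag. Presence/absence
agreement per diagnostic ion scores 2, an additional strong/weak category
match scores 1, the D₁/E₁ ratio test (> 2 ⇒ 1,3; < 0.5 ⇒ 1,4; else
inconclusive) scores 1, and each reference-spectrum intensity comparison
scores 1. All thresholds and weights are invented operationalizations of
qualitative vocabulary — the original comparative readings were expert
judgments, not numbers — and they live in one place (`cid_thresholds()`) so
a user can disagree with them. Co-optimal candidates are reported as an
explicit ambiguity; the package never breaks a tie silently.

Per-linkage confidence is the fraction of informative diagnostics
concordant with the called linkage, which makes it monotone in concordance
by construction. Reference spectra are optional: absolute presence/absence
rules carry all the weight without them, which is the right default for
simulated spectra and a deliberate simplification for real ones, where
instrument-dependent intensities are exactly why comparative references are
used at the bench.

With clean simulated spectra the diagnostics overdetermine the answer
(³,⁵A alone fixes every linkage), and the tests verify exhaustive recovery:
16/16 at DP 5 and 56/56 over DP 4–6. Under the documented noise model
(m/z jitter σ = 0.1 Da, 10 uniform noise peaks below 5% intensity) DP-5
recovery stays ≥ 95% across 100 seeds — a regression bound on the scoring
function, not a claim about instruments.

## Synthetic data

`generate_mlg()` is a unit-level generative grammar, because MLG fine
structure is discussed in cellooligosaccharide units joined by single 1,3
bonds, not residue by residue. Defaults, chosen once:

* `p_cellobiosyl = 0.01` — keeps the realized cellobiosyl unit frequency
  (≈ 0.99% after forcing) under the 2% bound reported for barley, and makes
  the analytic DP-5 mass fraction after GH12 digestion,
  $5q / (5q + (1-q)(0.697 \cdot 3 + 0.303 \cdot 4))$, equal 1.5% — the
  observed yield of the minor fraction;
* `triosyl_tetraosyl_ratio = 0.697:0.303` — a literature-typical barley
  ratio; the source material for this workflow does not print one, so this
  is an assumption and is flagged as such;
* `force_triosyl_after_cellobiosyl = TRUE` — honors the placement of
  cellobiosyl units on the nonreducing side of cellotriosyl units; a free
  mode exists to explore what a relaxed placement would produce (DP-6
  G3G4G3G4G4G fragments), documented as extrapolation. A cellobiosyl drawn
  at the final unit slot is redrawn (there is no room for its forced
  follower); with 10⁴-unit chains this edge case is negligible.

Chain ends are the one systematic artifact of finite chains: the
nonreducing-terminal unit loses its 1,3 prefix (yielding a G4G/G4G4G stub)
and the reducing-terminal unit's last bond lacks a +2 residue for GH12
(yielding a DP (m+1) product, occasionally DP 5). Long chains (10⁴ units)
keep these below 0.01 percentage points of the DP-5 mass fraction.

`simulate_spectrum()` draws strong-band (0.5–1.0) and weak-band (0.02–0.08)
intensities for feasible ions, omits infeasible ions entirely, jitters m/z,
adds uniform noise peaks and renormalizes. What it does *not* emulate about
real spectra — isobaric interferences beyond the modeled series, detector
saturation, chemical noise structure, instrument-dependent intensity
response — bounds what passing tests mean: they validate the logic of the
comparative method, not its robustness on any particular instrument.

All randomness flows through one seeded generator per call, isolated from
the caller's RNG state; the reference fixtures under `inst/extdata/`
(labelled synthetic in their filenames) regenerate byte-identically from
pinned seeds, and a test checks that.

## Problem sizes and numerical choices

The shipped analyses and tests use: 40 chains × 10⁴ units (4 × 10⁵ units)
for the population digest — sized so the binomial sampling error of the
cellobiosyl count (≈ 0.02 percentage points on the DP-5 mass fraction) is
well inside the two-significant-figure resolution at which that fraction is
reported; 1,000 random chain × rule-set pairs for conservation/idempotence
properties; exhaustive enumeration to DP 12 at most (4,096 candidates
maximum, brute force by design). Annotation ties break toward the lower-m/z
ion; candidate enumeration returns lexicographic notation order; digest
products sort by DP then notation — every ordering is deterministic.
Degenerate inputs are rejected loudly (DP-1 PMAA, empty peak lists for
inference, inconsistent profile/DP combinations) rather than coerced.

## Known limitations

* Linear 1,3/1,4 β-glucans only; no branches, no other monosaccharides, no
  anomeric chemistry beyond β.
* Subsite rules capture limit-digest specificity; relative activities
  between substrates (a kinetic property) are out of scope, so wet-lab
  activity tables can only be checked as activity vs no activity.
* The GH16 rule set's permission to cleave 1,3 bonds in MLG context is
  undetermined by the available product data (see above).
* PMAA recovery bias is acknowledged but not modeled; ranking is
  shape-based least squares.
* D/E/G/V elemental compositions are the simplest consistent assignment,
  not an independently confirmed one; the anchored mode exists precisely
  because a user with calibrated spectra may prefer to bypass them.
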