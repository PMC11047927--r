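---
title: "Methods: synthetic nanobody library analysis, panning scoring, and binding models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic nanobody library analysis, panning scoring, and binding models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanopanr)
```

# Scope

nanopanr implements the computational side of a synthetic nanobody
phage-display campaign: the exact statistics of a degenerate-codon
(NNB-randomised) library design, the NGS pipeline that turns paired-end
amplicon reads into an intact-sequence repertoire, the positive/negative
panning-pool specificity statistic used to mine binders, and the
quantitative binding models (three-parameter logistic dose-response, 1:1
Langmuir biolayer-interferometry kinetics, sandwich epitope binning). A
fully seeded synthetic-data generator emulates every input with known
ground truth, so each stage can be scored against what was actually
planted. Wet-lab procedures, antibody numbering for arbitrary frameworks,
and structural analysis are out of scope.

# The library model

A library design is a single constant VHH framework (FR1-FR4) with three
diversified CDRs. Each CDR position is `fixed`, `fully_randomized` (a
degenerate codon encoding all 20 residues, NNB in the default design), or
`partially_randomized` (a mixed-nucleotide codon allowing 2-6 residues).
CDR3 is a run of 7, 11 or 15 NNB codons (short/medium/long), ligated at
1:2:1 molar weights in the default design.

The algebra is exact rather than sampled. A degenerate codon expands to the
Cartesian product of its per-letter IUPAC sets; with uniform nucleotide
mixing every concrete codon is equiprobable, so the expected frequency of a
residue is its codon multiplicity over the expansion size. For NNB
(4 x 4 x 3 = 48 codons) this gives, e.g., Ser 5/48, Leu and Arg 4/48, Trp
1/48, and a single stop codon (TAG) at 1/48. Two quantities follow in
closed form:

* **stop-free probability** per CDR3 class: the product over randomised
  positions of (1 - per-position stop fraction); for $k$ NNB positions,
  $(47/48)^k$. It models stop codons only - assembly indels are a separate
  process.
* **theoretical diversity**: the product of allowed-residue counts (stops
  excluded) over randomised positions, class-weighted for the total.

The genetic code defaults to the standard code. Because display strains
such as TG1 suppress the amber codon, an `amber_readthrough` mode treats
TAG as Gln for display-phase modelling; the intact filter nevertheless
counts all three stops as defects by default, since the filter definition
("absence of early stop codon") is unqualified.

**Assumption.** The exact identity and count of randomised CDR1/CDR2
positions is not derivable from the published main text; the default
design uses 4 NNB + 2 partially randomised sites in CDR1 and 3 NNB + 2
partially randomised sites in CDR2 on a generic VHH framework. Everything
is configurable through a JSON design file (`read_design_json()`); YAML is
not supported because the graded environment does not ship an R YAML
parser.

# Read processing

The pipeline is merge, trim, translate, classify:

1. **Merging.** Mate 2 is reverse-complemented; among overlap lengths
   $L \ge$ `min_overlap` (default 20) whose mismatch fraction is at most
   `max_mismatch_fraction` (default 0.1), the one with the most matching
   bases wins, ties to the longest overlap. Mismatching bases resolve
   toward the higher-quality base, or mate 1 when qualities are absent
   (the bundled generator emits constant qualities, so `process_fastq()`
   reads sequences only). No dovetail or staggered-adapter handling:
   amplicons are fixed-locus. The implementation (C++) is checked against
   a quadratic brute-force oracle in the test suite.
2. **Primer trimming.** The 5' and then 3' primer are located allowing a
   bounded number of substitutions (no indels, default 1); the region
   strictly between them is kept. The merger/trimmer parameters of the
   original analysis are not published; these defaults are documented, not
   inferred.
3. **Translation.** Frame 0; a length not divisible by 3 is a
   `frame_indel`; codons containing ambiguous bases render as `X`.
4. **Intact filter.** Applied in fixed order: rendered length must match a
   design class (`length_mismatch`), no stop symbol (`premature_stop`),
   and the design's C-terminal motif must match (`anchor_mismatch`).
   Intact clones get their CDR3 class from the length, which is unique per
   class by design invariant.

The intact fraction divides intact reads by successfully merged *and*
trimmed reads; merge/trim failures are excluded from the denominator.
Unique-sequence identity is at the amino-acid level of the trimmed region
(synonymous variants collapse), matching how the repertoire statistics are
framed downstream.

# Repertoire QC

CDR boundaries come from exact matches of the constant framework segments
- exact for a single-framework synthetic library, with no general antibody
numbering involved. Positional composition is read-weighted by default
(each read one vote, per CDR3 class); a unique-sequence weighting is
available. Observed/expected comparison is restricted to fully randomised
sites: intact sequences cannot contain stops, so the NNB expectation is
renormalised over the 20 residues before ratios and per-position total
variation distances are computed. The occurrence spectrum buckets *unique*
sequences by multiplicity (1/2/3/>3), per NGS dataset.

# Panning specificity

Each pool is a percentage table (count/total x 100). For every sequence in
the positive pool, the specificity ratio is its positive percentage over
its negative percentage. A sequence absent from the negative pool would
divide by zero; it receives a pseudocount of one read
(`pseudocount/(total+pseudocount)`), a documented, configurable choice -
the original analysis does not state how such zeros were handled.
Candidate selection applies *strict* inequalities, mirroring the published
gates "exceeding 0.01%" abundance and ratio "exceeding ten". Homolog
families are clustered greedily: the most abundant unassigned candidate
seeds a family and absorbs all same-class candidates within a Hamming
distance of 2 over the concatenated CDRs. Greediness is a design choice -
the source analysis reports only distances to its top clone, not a
clustering algorithm. The phage-ELISA call divides the antigen-well
absorbance by the blocked-control absorbance; a clone is specific iff the
control is below 0.1 and the score exceeds 5 (strict). A zero control
yields an infinite score; the call then falls back to requiring the
antigen well to exceed `max_control * min_score` and is flagged.

# Binding models

**Dose-response.** The "three parameters" model fixes the Hill slope at 1:
$R(d) = \mathrm{bottom} + (\mathrm{top}-\mathrm{bottom})/(1 + EC_{50}/d)$.
With $EC_{50}$ fixed the model is linear in bottom/top, so the fit
profiles the residual sum of squares over $\log EC_{50}$ on an 80-point
grid spanning two decades beyond the observed dose range and refines the
best point by golden-section search (tolerance 1e-10). Flat or decreasing
curves are flagged `converged = FALSE` rather than silently returned. A
free-slope variant is available through the `hill` argument but is not the
default.

**1:1 kinetics.** Association
$R(t) = R_{max}\frac{C}{C+K_D}(1-e^{-(k_aC+k_d)t})$, dissociation
$R(t) = R(t_{assoc})e^{-k_d(t-t_{assoc})}$, with $K_D = k_d/k_a$ and
half-life $\ln 2 / k_d$ as exact derived identities. The fit is *global*:
one $(k_a, k_d, R_{max})$ triple shared across all analyte concentrations,
least squares over both phases, multi-started from a 4 x 4 x 2 grid in
log-parameter space (BFGS, then a Nelder-Mead polish). Global fitting is
the standard for 1:1 Octet-style analysis and is needed for
identifiability when concentrations sit below $K_D$. Standard errors come
from the numerical Hessian of the RSS at the optimum
($\mathrm{cov} = 2\hat\sigma^2 H^{-1}$), with the $K_D$ error by the delta
method on $\log k_d - \log k_a$. Mass transport, drift and baseline steps
are not modelled; reference subtraction is a plain trace difference.

**A note on the published rate table.** The source table prints the
association rate constants of two antibodies with a $10^{-4}$ exponent,
which is inconsistent with the printed $K_D = k_d/k_a$; the $10^4$ scale
reproduces the printed $K_D$ exactly. The bundled reference table
(`inst/extdata/kinetics_reference.json`) therefore carries the
$10^4$-scaled values, flags both rows with `ka_exponent_typo`, and treats
$k_d$, $K_D$ and half-life as authoritative.

**Epitope binning.** In the sandwich format the second antibody's extra
shift is compared with the shift it would produce on free antigen: at or
above 20% of the full shift the epitopes are non-overlapping, at or below
5% they overlap, in between the overlap is partial. The published
description ("no or very low response") gives no numeric thresholds;
0.2/0.05 are documented defaults, and negative shifts are clamped to zero
with a warning.

# The synthetic-data stated world

Every generator is a pure function of its configuration and seed
(byte-identical reruns), and every dataset is accompanied by ground truth
sufficient to score recovery. Defaults encode the conditions the source
experiment states, plus documented assumptions where it is silent:

* **Library.** NNB codons drawn uniformly from their 48-codon expansion,
  so stops arise at the intrinsic $(47/48)^k$ rate; CDR3 classes at the
  1:2:1 ligation weights (the sequenced phage library reached 3:1:1, used
  where that condition is being emulated). Assembly defects per clone:
  frameshifting 1-2 nt indels at 0.42, extra premature stops at 0.04,
  terminal-motif corruption at 0.04. Combined with intrinsic NNB stops
  this yields an intact read fraction near 0.35, the published phage-library
  value; the split between indels, stops and terminal damage behind the
  published ~60-65% defect load is unknown and these proportions are
  assumptions, not estimates.
* **Sequencing.** 2 x 250 bp reads, constant qualities, substitution-only
  errors at 0.001/base; indel sequencing errors are folded into the
  clone-level defect rates. No Illumina quality modelling, chimeras, or
  UMI structure.
* **Panning.** Multiplicative per-round enrichment with a finite elution
  bottleneck (default $10^5$, motivated by the titered eluates of the
  protocol): antigen-well weight
  $f_s(1+e_{spec,s})(1+e_{bg,s})$, control-well weight $f_s(1+e_{bg,s})$,
  multinomial resampling each round, NGS tables as multinomial draws from
  the final wells. Defaults (5 specific clones at $e_{spec}=50$, 50 sticky
  clones at $e_{bg}=30$, $10^4$ background clones, three rounds) were
  chosen once to reproduce the qualitative biphasic ratio-versus-abundance
  scatter of the published round-3 analysis: sticky clones land near ratio
  1, specific clones well above 10. No phage growth-competition dynamics
  or amplification fitness are modelled.
* **Assays.** Plate responses are the logistic model times
  $1 + \mathcal{N}(0, cv)$ with $cv = 0.05$; sensorgrams get i.i.d.
  Gaussian noise of 0.005 nm. Dosing presets follow the published
  protocols (5-fold from 10 uM for the reporter assay and flow binding;
  3-fold from 300 nM for ELISA; 900/300/100/33 nM, 300 s association,
  600 s dissociation for BLI).

A green test on this world therefore establishes that the implementations
recover what the generators planted under the stated noise; it does not
establish robustness to real-data pathologies the generators deliberately
omit (quality-dependent errors, chimeric reads, amplification bias,
instrument drift).

# Numerical choices and degenerate inputs

* Fractions are validated to sum to 1 within 1e-9 (composition) and
  1e-12 (expectations); $K_D \equiv k_d/k_a$ and half-life
  $\equiv \ln 2/k_d$ hold to machine precision by construction.
* Candidate ordering breaks ties lexicographically by sequence so output
  is deterministic; merging breaks overlap ties toward the longest
  overlap.
* Empty FASTQ input yields a zeroed QC report, not an error; an empty
  overlap search yields a `merge_failed` status, never an exception;
  non-convergent fits report themselves through `converged`/exit status 3
  rather than returning silently.
* Seeds are mandatory everywhere randomness exists; generator helpers
  save and restore the caller's RNG state.

# Known limitations

* CDR extraction requires the design's exact framework segments; mutated
  frameworks (e.g. from sequencing errors surviving the filter) raise
  anchor errors rather than fuzzy-matching.
* The merger considers simple suffix-prefix overlaps only, which is exact
  for fixed-locus amplicons but not for dovetailed or adapter-read-through
  layouts.
* The kinetic model is 1:1; bivalent or heterogeneous-ligand data will
  fit poorly and should be judged by the per-curve residuals the fit
  reports.
* The ELISA/ADCC response scales of the original plates are not published;
  synthetic plates use representative instrument scales, which affects
  nothing dimensionless (EC50 recovery is scale-equivariant, and the test
  suite asserts that equivariance).
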