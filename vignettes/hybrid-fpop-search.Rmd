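---
title: "Hybrid variable-modification and mass-offset searching of FPOP data"
author: "fpopseek"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid variable-modification and mass-offset searching of FPOP data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fpopseek)
```

## The problem

Fast photochemical oxidation of proteins (FPOP) exposes proteins to hydroxyl
radicals that irreversibly oxidize solvent-accessible side chains; the extent
of modification at each site reports on protein structure.  Because hydroxyl
radicals modify nearly every amino acid, and several distinct products occur
per residue, database searching of FPOP tandem-MS data faces a combinatorial
explosion.  For a peptide with $s$ modifiable sites and $k$ possible
modifications per site, a conventional variable-modification search must
consider on the order of $(k+1)^s$ peptidoforms: a 20-mer with two possible
modifications per residue already has $3^{20} \approx 3.5\times10^9$
configurations.  At whole-proteome scale this is intractable and, just as
damaging, the enormous candidate space inflates score thresholds and costs
sensitivity.

## The hybrid search space

`fpopseek` restricts the space with a two-tier scheme:

* **Variable modifications** (the common products, e.g. oxidation
  +15.994915 Da on selected residues, and protein N-terminal acetylation
  +42.0106 Da) are enumerated combinatorially, up to `maxVarMods = 3` per
  peptide, one delta per site.
* **Mass offsets** (the rare products: di-/trioxidation, carbonylation,
  His-ring transformations, decarboxylation, CO/CO2 loss, Arg deguanidation,
  and the carbamidomethyl-adjusted Cys oxidations) are matched at the
  precursor level, **at most one non-zero offset per peptide**, and localized
  afterwards by rescoring with shifted fragment series.

Every variable-modification configuration can combine with any one
applicable offset, so a peptide carrying several common modifications plus
one rare one is findable; a peptide carrying two rare modifications is, by
construction, not in the space.  That pruning is the method's stated
trade-off: it is what keeps the space (and the score threshold) small.

For counting, `countConfigurations()` computes the capped
variable-modification count $V$ by polynomial (occupancy-DP) multiplication
and adds, for each offset $o$, the number of configurations retaining a free
eligible residue, $V - B_o$, where $B_o$ counts configurations that occupy
every $o$-eligible site.  All counts are exact in double precision (they are
far below $2^{53}$).

One subtlety found during implementation: the intuition "moving a
modification from the offset list to the variable list never decreases the
hybrid count" is true at unlimited cap (each offset application maps
injectively to a placement at the first free eligible site) but **false**
under a tight cap — with sequence `MMM`, one variable mod `a` on M, one
offset `b` on M and `maxVarMods = 1`, the hybrid space has 8 forms but
promoting `b` to a variable mod leaves only 7.  The property test therefore
asserts monotonicity at unlimited cap only.

## Masses and chemistry

Monoisotopic residue masses, water 18.0105646 Da, proton 1.00727646688 Da.
The rare-offset table stores the conventionally printed 4-decimal deltas;
derived values are reproduced from elemental masses (O = 15.994915,
H = 1.0078250319, C = 12 exactly): dioxidation $2\mathrm{O} = 31.9898$,
CO2 loss $-(\mathrm{C}+2\mathrm{O}) = -43.9898$, carbonylation
$\mathrm{O}-2\mathrm{H} = 13.9793$.  Cysteine is fixed-carbamidomethylated
(+57.021464 Da), so Cys oxidation offsets are expressed relative to the
alkylated residue: `adjustOffsetsForFixedMods()` subtracts the fixed delta
for any offset whose residue set lies entirely inside a fixed modification's
residue set, giving $2\times15.994915 - 57.021464 = -25.0316$ and
$3\times15.994915 - 57.021464 = -9.0367$ at 4-decimal rounding.  These only
round correctly when computed at five or more decimals, which is why the
package carries full-precision elemental masses internally.

Digestion uses *stricttrypsin*: cleavage C-terminal to K/R with **no**
proline exception, up to 2 missed cleavages, peptide length 7–50, and
N-terminal Met clipping (peptides from the clipped protein form are flagged
as protein-N-terminal and are the only ones eligible for N-terminal
acetylation).  Reversed full-protein sequences serve as decoys
(`rev_` accession prefix by default).

## Scoring and localization

Only b/y ions are modeled, at fragment charges 1 up to
min(`maxFragmentCharge` = 2, precursor charge − 1) — tryptic HCD-style
spectra are dominated by that signal.  The score
is an X!Tandem-style hyperscore,

$$ \mathrm{score} = \ln\!\big(N_b!\; N_y!\; \max(1, \textstyle\sum I_b)\;
\max(1, \textstyle\sum I_y)\big), $$

with factorials capped at $20!$ and each theoretical ion matched to its
nearest peak within ±0.02 Da (ties to the lower-m/z peak).  Precursor
tolerance is ±20 ppm.  These defaults are typical for Orbitrap-class data;
the source study does not print its tolerances, so they are declared here
rather than inherited.

A candidate with a non-zero offset is rescored with the offset placed at
each eligible free site in turn; fragments containing the site shift by the
offset mass.  The best-scoring site is reported; sites tying within $10^{-6}$
leave the offset "unlocalized".  Candidates matching fewer than
`minMatchedPeaks = 4` fragments are discarded entirely — without that floor,
zero-evidence candidates on junk spectra would be promoted by the
deterministic tie-break (which prefers targets) and leak through
target-decoy filtering.

The fragment index stores, per variable-mod-resolved peptidoform, the
neutral b/y fragment-mass arrays plus a binned fragment-m/z entry table
(`binWidth` = 0.02 Da); offsets are applied at query time, so index size is
independent of the offset list.  At dataset scale `searchDataset()` omits
the entry table (`storeEntries = FALSE`) and scores candidates directly from
the per-form arrays after a binary-search precursor window per offset — the
results are identical, and an exhaustive `method = "naive"` scorer is kept
as an in-package oracle: both methods must return identical rank-1 PSMs
(tested on every instance up to 500 peptidoforms).

## Group-based FDR

PSMs are split into **unmodified**, **assigned** (every modification on the
PSM appears in the user's list, default `M:15.9949,n:42.0106`), and
**other** (anything else, including any unlisted non-zero offset).  Met
oxidation defaults to the assigned group because its large artifactual
background would otherwise inflate the confidence of the rare-modification
group.  Within each group, q-values are decoy-based: sort by score, estimate
FDR as #decoys / max(1, #targets) at each threshold (tied scores share a
threshold), take the running minimum from the bottom.  A PSM passes at
q ≤ 0.01 within its own group; decoys never pass.  The pooled variant
(`regularFdrFilter()`) is provided for comparison — when modified PSMs are a
minority with a larger effective search space, the pooled threshold is
appropriate for neither class.  PeptideProphet-style mixture modeling and
protein-level FDR are deliberately out of scope; the decoy-count q-value
implements the same 1%-PSM contract in a directly testable form.

## The synthetic world

No real raw data ships with the package; `generateBenchmark()` states a
synthetic world with the qualitative structure reported for in-vivo FPOP
datasets and known ground truth:

* 50 proteins of mean length 300 (UniProt-average residue frequencies,
  K+R ≈ 11% so tryptic peptides are abundant), 2000 spectra, seed 42;
* modified spectra a minority — 20% by default (the real fraction is not
  printed anywhere; 20% is a declared choice, not a reproduced value);
* Met oxidation 50× more abundant than each other modification type, inside
  the reported 26–90× band.  Types are drawn first by abundance weight and
  the host peptide second, so the ratio reflects the profile rather than
  residue availability;
* extra events (up to 3 total, at most one rare) attempted with probability
  0.35, skipped when the drawn type has no free eligible residue — this
  yields multiply-oxidized peptides without distorting the type ratio;
* 2% of modified peptides carry two distinct rare modifications, the hybrid
  scheme's designed blind spot;
* rendering: charge-1 b/y peaks, log-normal intensities, m/z jitter
  sd 0.003 Da, 15% peak dropout, 30 uniform noise peaks, precursor jitter
  3 ppm, precursor charge 2 (70%) or 3 (30%).

The generator does **not** emulate chromatography, isotope envelopes,
co-isolation or instrument-specific noise, so a green benchmark establishes
the correctness of the search/FDR machinery on calibrated, moderately noisy
spectra — not performance on real raw files.

## Numerical choices and degenerate inputs

* Exact score ties in rank-1 selection: higher matched-peak count, then
  lexicographic peptide, then target before decoy, then lower peptidoform
  id — fully deterministic, so repeated runs are byte-identical.
* Localization ties within $10^{-6}$ return "unlocalized" plus the tied set.
* A group with zero targets gets q = 1 throughout; empty inputs give empty
  outputs of the right shape.
* Peptides shorter than 7 residues, or proteins with no tryptic peptide in
  bounds, simply contribute nothing.
* Offsets colliding within 0.0005 Da on a shared residue after fixed-mod
  adjustment raise a warning (they are then indistinguishable at the default
  precursor tolerance).

## Known limitations

Only b/y ions; no neutral losses, isotope-error correction, semi-enzymatic
digestion, I/L disambiguation, protein inference, or mass recalibration
(synthetic data are generated calibrated instead).  Configuration promotes
per-modification caps to a single global `maxVarMods`; for the standard
workflow family this is equivalent (the terminal acetyl site is unique, so
its cap of 1 is implied).  When oxidation residues are promoted to variable
modifications, those residues are removed from the oxidation offset's
residue list and the remainder stays searchable as an offset — whether
production pipelines retain or drop the remainder is not documented
anywhere, so retaining is this package's declared choice.
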