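---
title: "Proteoform-resolved PRM quantification of lamin A and farnesylated progerin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Proteoform-resolved PRM quantification of lamin A and farnesylated progerin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prmlamin)
```

## The measurement problem

Prelamin A matures through four C-terminal processing steps:
farnesylation of the CAAX-motif cysteine (CSIM), proteolytic removal of
the last three residues (AAX), carboxyl O-methylation of the now
C-terminal farnesyl-cysteine, and a final Zmpste24 cleavage that removes
15 residues — modified cysteine included — to yield mature lamin A. The
HGPS deletion (50 residues of exon 11) removes the Zmpste24 site, so
progerin keeps its farnesylated, O-methylated C-terminus permanently.

The consequence for measurement is that the proteoforms differ only at
their C-termini and in one internal 50-residue stretch. A tryptic digest
therefore contains peptides of three diagnostic kinds:

* peptides shared by all proteoforms — an *internal control* (IC,
  `TVLCGTCGQPADK`) reporting the total lamin A pool;
* peptides inside the deletion — the *lamin A signature* (LA,
  `SVGGSGGGSFGDNLVTR`), absent from progerin;
* C-terminal peptides carrying the farnesyl + O-methyl cysteine — unique
  per proteoform because the junction sequence differs (mouse zFP
  `SQSSQNC`, mouse progerin mFP `AAGGAGAQSSQNC`, human progerin hFP
  `ASASGSGAQSPQNC`).

`build_proteoforms()` encodes the processing rules, `tryptic_digest()`
the protease specificity (cleave after K/R, suppressed before Pro;
protein C-terminal peptide always kept), and `assign_signatures()` /
`select_surrogates()` the combinatorial argument above. Uniqueness is
evaluated *within the supplied proteoform set*, not against a whole
proteome: the panel discriminates proteoforms of one gene product, and
unprocessed prelamin A — a transient intermediate that shares every
internal peptide with the farnesylated form — is deliberately excluded
from the discrimination set (`mature lamin A`, `farnesylated prelamin A`,
`progerin` for mouse; `mature lamin A`, `progerin` for human). With it
included, no unmodified peptide could ever be unique to the farnesylated
form, which is biologically uninformative. Selection policy keeps fully
tryptic peptides of 6–25 residues (shorter ones are rarely retained or
specific on reversed phase; longer ones ionise and transmit poorly) and
returns, per proteoform, the candidates with the smallest containing
subset; whether the original selection used explicit length or
hydrophobicity filters is not documented, so these bounds are this
package's own, stated default.

## Mass calculus

All masses are monoisotopic. A neutral peptide is the residue-mass sum
plus one water; ions are `(M + z·m_proton)/z` with `m_proton =
1.007276`. Modifications are additive deltas on residues:
carbamidomethyl +57.021464 (fixed alkylation of every non-farnesylated
Cys), O-methyl +14.015650 and farnesyl +204.187801 (C15H24) stacked as
*two* modifications on the C-terminal Cys so that the farnesyl can be
toggled independently — the species monitored after farnesyl neutral
loss is defarnesylated but still O-methylated, which is why
`fragment_mz()` takes an explicit `defarnesylated` flag rather than an
implicit rule. Heavy labels are per-residue counts of 13C (+1.0033548)
and 15N (+0.9970349), so the heavy–light spacing is reproducible from
the counts alone and fragments shift only when they contain the labelled
residue (`add_heavy_companions()` recomputes every trace from the
labelled peptide instead of shifting numbers, and warns when a monitored
fragment misses the label).

Rounding for table display is half-even to 4 decimals (`mz_round()`);
internal arithmetic stays at full double precision. The regenerated
panels agree with their reference values within ±0.0015 Th, which
absorbs last-digit rounding jitter in the references themselves (the
heavy hFP precursor appears as both 743.8700 and 743.8701 there; the
package does not force one).

## Assay patterns

`lamin_panel()` builds three panels from peptide definitions alone:

* **MS3 panels** (mouse and human relative): each peptide's 2+ precursor
  is fragmented, an intense fragment — for farnesylated peptides the
  farnesyl neutral-loss ion, the dominant product — is selected again,
  and one fragment of that selection is monitored. The two traces of a
  peptide are summed into one signal (`combine_traces()`); the tables
  join them with "+" and the corresponding chromatograms show a single
  XIC per peptide, so summation is the interpretation implemented and
  asserted.
* **MS2 panel** (human absolute): two fragment XICs per precursor read
  directly from MS2 scans, duplicated for the heavy standards IC*
  (6×13C+2×15N Lys), LA* (6×13C+4×15N Arg) and hFP* (3×13C+1×15N
  N-terminal Ala), time-scheduled at 0–35 / 35–70 / 70–162 min with
  light/heavy partners sharing a window (isotopologues co-elute).

Scheduling is optional — the mouse panel is unscheduled, matching its
source — and `schedule()` allows overlapping windows.

## Quantification

`extract_xic()` matches scans level-by-level along the selection path
and sums peaks within ±10 ppm (Orbitrap-class accuracy; configurable) of
the monitored m/z; a matching scan with no peak contributes 0, while *no
matching scan at all* yields an empty trace — absence of acquisition and
absence of signal are kept distinguishable. Integration is trapezoidal
over the scheduled window by default; a local-maximum peak-bounded
variant (boundaries extend from the apex while intensity is
non-increasing) is available but vendor-style peak picking is not
reverse-engineered.

Relative mode normalises areas to IC = 100. Absolute mode computes
`amount = (light/heavy) · spike_fmol · 100/protein_µg` (fmol per 100 µg
protein extract) and calls a status per run: `not_detected` when the
light area is at or below the noise floor (default 0 — the synthetic
generator keeps chemical noise out of the monitored windows, so any
non-zero area is signal; raise it for real data), `detected_below_loq`
when light/heavy falls below the LOQ ratio (default 0.01; the
quantification limit is known to exist for progerin in white blood cells
but is not numerically defined anywhere, so this is a stated package
default), and `quantified` otherwise. Replicate summaries report mean,
sample sd and CV% = 100·sd/mean. Because spiked peptide standards cannot
correct for peptide losses upstream of the spike (e.g. extraction from
the gel matrix), "absolute" amounts are standardised rather than truly
absolute; the package echoes this caveat rather than correcting for it.

## The synthetic-run generator

`simulate_run()` emulates a time-scheduled PRM acquisition: one scan per
cycle (default 1 s) per selection path inside each row's RT window;
the monitored ion of each trace receives
`response · fmol_on_column · dnorm(rt; apex, σ) · fraction · (1 + ε)`
with `ε ~ N(0, cv)`, plus uniformly placed chemical-noise peaks kept
≥0.05 Th away from monitored ions. Because the Gaussian integrates to 1
and trace fractions sum to 1 per peptide, the combined area of a peptide
is `response · fmol` exactly in expectation, which makes closed-form
oracles possible: the generator's per-scan bookkeeping must equal
`extract_xic()` output point for point (asserted at zero tolerance), and
noiseless dense runs must recover amounts to float precision.

Scenario fixtures encode the study conditions: HGPS fibroblasts with
progerin 43 and lamin A 133 fmol/100 µg versus 224 in controls (those
means, with IC carrying their sum, are the generator's truths); heavy
spikes of 50 fmol per standard into 100 µg of digest (a typical
mid-curve spike; the actual spike levels are not printed anywhere);
white-blood-cell scenarios where progerin sits below the LOQ ratio
(0.3 fmol against the 50 fmol spike) or at zero; and mouse scenarios
with LA/IC ≈ 1/3 (mutant) or ≈ 1 (wild type). Elution apexes sit
centrally in each scheduled window with σ = 0.15 min, a typical
nano-LC peak width.

What the generator does *not* emulate — and therefore what passing tests
cannot establish about real data: peak tailing and retention drift,
isotope envelopes and co-isolated interferences, ion-statistics
(shot-noise) scaling, matrix-dependent response factors, and losses
during sample preparation. Tests on synthetic runs validate the
*calculus and bookkeeping* of the pipeline, not instrument performance.

## Numerical and problem-size choices

Deterministic seeding: every stochastic step draws from one seed;
replicate *i* uses `seed + i - 1`. End-to-end recovery tests run the
full-length scheduled acquisitions (about 19,000 scans per run) in
memory; mzML round-trips are exercised on coarser-cycled runs (5–10 s,
about 1,000–2,000 scans), and the Monte-Carlo precision check (100
seeded triplicates at 5% noise, mean empirical CV under 20%) uses a
reduced single-pair panel with a 5 s cycle — sizes chosen so the whole
suite stays fast while every code path is hit at realistic densities.
mzML files are written with 64-bit uncompressed arrays (peak values
round-trip bit-exactly) and MS3 selection paths as two-element precursor
lists, the standard multistage encoding; an independent mzML reader is
used in the tests to cross-check the files this package writes.

## Known limitations

* Proteome-wide surrogate uniqueness is out of scope (no BLAST-style
  screening); uniqueness holds within the modelled proteoform set.
* Bundled sequences are synthetic stand-ins with correct landmarks but
  arbitrary filler; analyses of real samples should supply database
  sequences via `read_fasta()`.
* One heavy hFP* reference trace value could not be reconciled with the
  row's own label definition (it differs from the light trace by the
  Lys-label delta although hFP* is Ala-labelled); the package emits the
  value implied by the label chemistry, which the hFP* precursor and b12
  fragment independently confirm.
* a/c/x/z ion series, average masses, isotope-envelope prediction and
  collision-energy modelling are not implemented.
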