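# prmlamin

Targeted mass-spectrometry (PRM) assay design and quantification for
**lamin A proteoforms**, including the permanently farnesylated progerin
variant that accumulates in Hutchinson-Gilford progeria syndrome (HGPS).

## The problem

HGPS is almost always caused by a synonymous *LMNA* mutation (c.1824C>T,
p.G608G) that activates a cryptic splice site in exon 11, deleting 50
residues of prelamin A — including the Zmpste24 cleavage site. The final
maturation step is therefore lost, and the mutant protein (*progerin*)
retains its C-terminal farnesylated, carboxymethylated cysteine. The
progerin : mature lamin A ratio tracks disease severity and is the readout
for therapies that suppress aberrant splicing or farnesylation, so it
needs to be measured specifically and quantitatively — which antibodies do
poorly. Parallel reaction monitoring (PRM) of proteoform-specific
*surrogate peptides*, with stable-isotope-labelled internal standards for
absolute quantification, is the non-immunological alternative this
package implements end to end:

* **Mass calculus** (`peptide_neutral_mass`, `precursor_mz`,
  `fragment_mz`, `neutral_loss_mz`, `apply_heavy_label`): monoisotopic
  masses and b/y fragment m/z for peptides carrying carbamidomethyl-Cys,
  C-terminal farnesyl (+204.187801 Da) + O-methyl (+14.015650 Da) Cys,
  and 13C/15N heavy labels; farnesyl neutral-loss ions and fragments of
  the defarnesylated species.
* **Proteoform model** (`build_proteoforms`, `tryptic_digest`,
  `assign_signatures`, `select_surrogates`): derives prelamin A,
  farnesylated prelamin A, mature lamin A (−18 residues) and progerin
  (Δ50, permanently farnesylated) from a precursor sequence, digests them
  in silico and picks the discriminating surrogate peptides (IC, LA,
  pre-LA, zFP, mFP, hFP).
* **Assay design** (`design_transitions`, `add_heavy_companions`,
  `schedule`, `lamin_panel`, transition CSV I/O): executable transition
  tables for the mouse relative (MS3), human relative (MS3) and human
  absolute (MS2 + heavy standards) panels.
* **Quantification** (`extract_xic`, `integrate_xic`, `quantify_runs`):
  XIC extraction from PRM runs (10 ppm default), trapezoidal
  integration, internal-control-normalised relative quantification, and
  isotope-dilution absolute quantification
  `amount = (light/heavy) · spike · 100/µg` in fmol per 100 µg protein,
  with replicate mean ± sd, CV% and
  not-detected / below-LOQ / quantified calls.
* **Synthetic runs** (`simulate_run`, `scenario_fixtures`, mzML I/O):
  a seeded generator of time-scheduled PRM runs with Gaussian elution,
  known truths and noise, so the whole pipeline is testable without
  instrument data.

The bundled prelamin A sequences are **synthetic stand-ins** (see
`?prelamin_sequences`): they carry every landmark the assay depends on
(CSIM terminus, processing arithmetic, deletion interval, all surrogate
peptides in native tryptic context) with arbitrary filler in between.

## Worked example

Regenerate the mouse relative MS3 panel and run the absolute human assay
on simulated HGPS-patient fibroblast triplicates:

```r
library(prmlamin)
lamin_panel("mouse_relative")
#> <assay_panel> mouse_relative (relative mode, 3 rows)
#>   IC    TVLCGTCGQPADK  703.8238 (2+)
#>          703.8238 > 430.2296  > 333.1769 (y3)
#>          703.8238 > 603.7657  > 933.4095 (y9)
#>   LA    SVGGSGGGSFGDNLVTR  783.8790 (2+)
#>          783.8790 > 690.8288  > 774.4104 (y7)
#>          783.8790 > 774.4104  > 602.3620 (y5)
#>   mFP   AAGGAGAQSSQNC  670.3374 (2+)
#>          670.3374 > 568.2435  > 886.4013 (b11)
#>          670.3374 > 1135.4797  > 993.4054 (y11)

fx <- scenario_fixtures("hgps_fibroblasts", seed = 7)
runs <- simulate_replicates(fx$panel, fx$truth, n = 3,
                            default_window = fx$default_window)
quantify_runs(runs, fx$panel)
#> <quant_result> absolute mode, 3 run(s)
#>   symbol n_runs      mean        sd cv_percent     status
#> 1     IC      3 175.67166 0.6024313  0.3429303 quantified
#> 3     LA      3 133.21832 1.3322214  1.0000286 quantified
#> 5    hFP      3  42.73859 0.2663720  0.6232586 quantified
```

Each panel row prints `precursor > [MS3 selection >] monitored m/z`; for
mFP the MS3 selection is the farnesyl neutral-loss ion (NL) and the
monitored fragments are computed on the defarnesylated species. The
quantification summary is in fmol per 100 µg protein extract: the
scenario's true amounts (IC 176, LA 133, hFP 43) are recovered within
~1% with triplicate CVs well under 20%, and the heavy standards (`IC*`,
`LA*`, `hFP*`) are reference channels, not analytes. In the
`control_fibroblasts` scenario the hFP (progerin) row instead reports
`not_detected`.

A command-line wrapper is installed at
`system.file("cli", "prmlamin", package = "prmlamin")` with `design`,
`simulate` and `quantify` subcommands (see `?prmlamin_cli`).

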