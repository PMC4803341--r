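---
title: "Methods: MaxQuant post-processing and Libra-style isobaric quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MaxQuant post-processing and Libra-style isobaric quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mqreport)
```

## Scope and model

`mqreport` post-processes a MaxQuant project directory. It does not touch
raw spectra or rescore identifications: its inputs are the `combined/txt`
tables MaxQuant already wrote, plus the FASTA databases used for the
search. Four reporting levels are produced — protein group, peptide,
modified site and MS/MS scan — following the minimum-reporting idea that a
shareable result needs far fewer columns than MaxQuant emits, and that the
columns worth keeping vary by MaxQuant version, which is why column
selection is rule-driven (exact titles and case-sensitive keyword
substrings) rather than hard-coded.

### Protein-group minimum reporting

A MaxQuant protein group lists every accession compatible with its
peptides. We retain only the accessions with the maximum unique-peptide
count and, among those, the maximum total-peptide count, preserving input
order; the first retained accession is the lead and receives gene/
description annotation. Ties (equal unique and total counts, or equal
group scores when a peptide maps to several groups) are broken by original
table order. The tie-break is a deliberate determinism choice: repeated
runs on the same input must produce diff-identical reports.

Decoy (reverse) and contaminant detection honours both the marker columns
(`Reverse`, `Potential contaminant`, or the older `Contaminant`) and the
`REV__`/`CON__` accession prefixes, because the conventions moved between
MaxQuant releases.

### Site tables

Residue PTMs are taken from MaxQuant's own `<PTM>Sites.txt` tables;
protein N-terminal modifications, which MaxQuant does not report as site
tables, are reconstructed from `msms.txt`: a scan whose modification
string names the configured N-terminal PTM supports a site when its
peptide sits at protein position 1, or position 2 of a Met-initiated
protein. Position 2 is admitted because initiator-methionine cleavage
leaves the biological N-terminus at residue 2; internal matches of the
peptide never create N-terminal sites. When the `Ile = Leu` option is set,
peptide-to-sequence matching treats I and L as equal, but reported windows
always show the catalog residues — matching keys are never written out.

Sites are *specific* when their localization probability is strictly
greater than the threshold (default 0.5), else *ambiguous*; a site whose
probability is absent is specific, because its position is fixed by the
peptide terminus rather than estimated from fragmentation. Only specific
sites are quantified. Sequence windows span `2*flank + 1` residues
(default flank 6, so 13 residues), padded with `_` beyond the termini —
the same convention MaxQuant uses, so windows drop into motif tools
unchanged.

## The quantification procedure

The pipeline order is fixed: impurity correction → channel calibration →
low-intensity filter → per-spectrum normalization → grouping → outlier
rejection → summary.

* **Correction.** Observed reporter intensities are modelled as
  `observed = M %*% true` with `M` the isotope-impurity matrix
  (columns = true channel, rows = observed channel; the loader rescales
  percent-style columns summing above 1, with a warning). The linear
  system is solved exactly rather than approximated by one-pass
  subtraction; this is stable for the diagonally dominant matrices vendors
  certify. Negative solutions, which arise at low signal, are clamped to 0
  to preserve non-negativity; clamp events are counted in the log.
* **Calibration.** Factor `f_c = mean(T)/T_c` per channel, where `T_c` is
  the channel's intensity total over all spectra. Equalizing to the
  across-channel mean avoids privileging any reference channel. The
  factors are always computed and exported (they are a useful view of
  experimental bias), but their *application* is switchable
  (`calibrate_channels`, default on): equal-total calibration assumes the
  samples were loaded equally, and in designs where total loading differs
  on purpose — a knockout versus wild type, or a validation fixture in
  which every protein carries the same skewed profile — applying it would
  remove exactly the biology being measured. This is the one place the
  package deliberately exposes a switch on the core algorithm, and the
  reason the planted-ratio validation below runs with calibration off.
* **Low-intensity filter.** Spectra whose summed intensity is at or below
  the threshold are excluded (not an error). The default threshold is 0 —
  only non-positive totals are dropped — because any other cut-off is
  instrument-dependent; the setting is exposed in the configuration.
* **Normalization.** Fractions per spectrum sum to 1 by construction;
  this per-spectrum sum normalization is what makes spectra of different
  absolute intensity comparable.
* **Outlier rejection.** Per channel within an entity's spectra, values
  farther than `k` population standard deviations (default `k = 1.96`)
  from the channel mean are removed. Removal is iterated until no value
  moves, so re-running the rejection on a retained set is a no-op — a
  useful algebraic property for testing and for incremental re-processing.
  With `k = 1.96` a single pass already removes nothing for groups of four
  or fewer (the population z-score is bounded by `(n-1)/sqrt(n)`), and we
  additionally skip groups under 3 spectra and channels with zero spread,
  so the iteration cannot cascade a small group away. A channel left empty
  by rejection falls back to its pre-rejection values and is flagged in
  the output.
* **Summary.** Median, mean and population SD per channel; medians are
  the headline value because they resist the heavy right tail of reporter
  noise. Replicates are quantified separately and merged by entity id as a
  full outer join — never pooled — so disagreement between replicates
  stays visible.

Protein-level grouping uses unique peptides only by default (spectra whose
peptide maps to more than one reported group are skipped); this is
switchable because all-peptide quantification is sometimes preferred for
coverage.

## The synthetic-data generator

`fixture_spec()`/`generate_project()` emulate a MaxQuant project: the four
`combined/txt` tables in a fixed column dialect (MaxQuant 1.5-style; a
second, smaller dialect with the older `Contaminant` column exercises
multi-version support), a UniProt-style FASTA with its header parse rule,
an identity correction matrix, and a matching reporting configuration.
Reporter intensities are drawn as
`base * profile[protein, channel] * lognormal(CV)` with a lognormal base
intensity per spectrum; a profile entry of 0 plants true zero expression.
Planted N-terminal sites place the supporting peptide at protein position
1 or 2; planted oxidation sites come with a MaxQuant-style site table and
supporting scans. A fixed seed makes the generated directory
byte-identical.

The default conditions — 20 proteins, 3 peptides each, 10 spectra per
peptide, 6 channels, noise CV 10%, two technical replicates, a small
admixture of decoy/contaminant groups — are desk-scale: large enough for
the medians and rejection steps to behave statistically, small enough
that the whole suite runs in seconds. Scaled-down variants (6 proteins,
4 channels) are used where the property under test does not need spectrum
counts.

What the generator does *not* emulate, and hence what passing tests do not
show about real data: chimeric spectra and co-isolation interference
(which compress real TMT ratios), intensity-dependent noise, missing
reporter channels, shared-peptide ambiguity beyond simple two-accession
groups, and retention-time or charge-state structure. Conclusions about
ratio accuracy on real instruments require spiked standards, not this
generator.

### Validation of ratio recovery

With every protein carrying the same planted 2:1:1:1:1:1 profile and 30
spectra per protein at CV 10%, the ratio of median fractions
(channel 1/channel 2) recovers 2 within ±5% for nearly all proteins —
run with calibration off, since here the loading difference is the planted
signal (see above). The complementary test plants *balanced* profiles
(half the proteins 2:1:1:1, half 1:2:1:1) so channel totals stay equal,
and verifies that the default pipeline — calibration applied — recovers
each protein's ratio. Note the ±5% band is tight relative to the sampling
noise of a median of 30 spectra at this CV (log-ratio SD ≈ 0.03), so the
per-protein in-band probability is high but not 1; the acceptance script
reports the observed recovery rate rather than asserting it per protein.

## Numerical and formatting choices

* All table values are kept as raw strings from file to file; numeric
  interpretation happens in the consumers. This makes
  read → write → read the identity, which is tested.
* Singular correction matrices are a fatal configuration error; a channel
  with zero total intensity across all spectra makes calibration
  undefined and is fatal with the channel named.
* The combined workbook is a single multi-sheet SpreadsheetML 2003 XML
  file: one sheet per table, names truncated to 31 characters and
  deduplicated, numeric-looking values typed as numbers, NaN-like values
  written as empty cells so spreadsheet software never sees `NaN`.
* Charts are emitted as SVG with a same-named TSV holding the plotted
  series; the TSV is the contract, the SVG is presentation.
* The processing log (INFO/WARN/ERROR, timestamped) is written into the
  output folder; on failure the log is still written — ending in the
  ERROR — and no `index.html` is produced, so the presence of the index is
  the success marker.

## Limitations

* Only MS2 reporter-ion quantification is implemented; MS3 or
  complement-ion strategies are out of scope.
* The annotated-spectra table relays MaxQuant's fragment annotation
  columns; no spectra are re-annotated.
* Header parse rules cover UniProt, Ensembl and NCBI dialects; other
  databases need a user-supplied rule file (the fallback keeps the first
  whitespace token as accession).
* Site positions are 1-based on the protein sequence as reported by the
  search; no remapping across isoforms is attempted.
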