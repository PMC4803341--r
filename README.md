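# mqreport

Post-processing, site reporting and isobaric quantification for
[MaxQuant](https://www.maxquant.org/) results.

MaxQuant writes its identifications as a `combined/txt` folder full of wide
tab-separated tables, it does not build report tables for protein
N-terminal modifications, and (in the versions this tool targets) it
extracts isobaric reporter-ion intensities without quantifying them.
`mqreport` closes those gaps for proteomics users who want shareable,
minimum-reporting-style results:

* **Table minimization** — columns are selected per table by configurable
  *exact* and *keyword* title rules, so one configuration file adapts the
  report to a MaxQuant version's column dialect.
* **Protein-group minimum reporting** — reverse (decoy) and contaminant
  hits are removed; each group keeps only the accessions supported by the
  most unique peptides (then most total peptides); the lead accession is
  annotated with gene and description parsed from FASTA headers (UniProt,
  Ensembl and NCBI presets ship with the package).
* **Site tables** — per-PTM tables with localization-probability
  classification (*specific* when p > 0.5, else *ambiguous*) and
  13-residue sequence windows padded with `_` at the termini. Protein
  N-terminal modification sites, which MaxQuant does not report, are
  recognized from `msms.txt` at protein positions 1 and 2 (initiator-Met
  cleavage).
* **Libra-style isobaric quantification** (TMT/iTRAQ) at protein, peptide
  and site level, per replicate, with isotope-impurity correction, channel
  calibration, per-spectrum normalization and sigma-based outlier
  rejection.
* **Descriptive statistics and a report bundle** — counts, distributions,
  replication assignment, SVG charts (each with an authoritative TSV data
  twin), a combined multi-sheet workbook, and an `index.html` entry page.

## The quantification model

For each MS/MS spectrum *s* with observed reporter intensities
**y**<sub>s</sub> over *n* channels:

1. **Impurity correction**: solve **y**<sub>s</sub> = *M* **x**<sub>s</sub>
   for the true signal **x**<sub>s</sub>, where *M* is the vendor's
   isotope-impurity matrix (columns = true channel); negative solutions are
   clamped to 0.
2. **Calibration**: channel *c* is scaled by
   *f<sub>c</sub>* = mean(*T*) / *T<sub>c</sub>*, where *T<sub>c</sub>* is
   the channel's total intensity over all spectra, so channel totals become
   equal. This removes technical loading bias; it can be disabled
   (`calibrate_channels`) for designs where total loading differs on
   purpose.
3. **Normalization**: fractions
   *p<sub>sc</sub>* = *x<sub>sc</sub>* / Σ<sub>c'</sub> *x<sub>sc'</sub>*;
   spectra whose total is at or below the low-intensity threshold are
   excluded.
4. **Grouping and outlier rejection**: spectra are assigned to their
   protein group (optionally unique peptides only), peptide, or specific
   site; per channel, fractions farther than 1.96 population standard
   deviations from the channel mean are rejected (iterated to a fixed
   point; groups under 3 spectra are untouched).
5. **Summary**: the median, mean and population SD of the retained
   fractions are reported per channel and replicate, then replicates are
   merged by entity id.

Because the result is a relative expression *value per channel* rather
than a ratio against a reference channel, true zero expression (e.g. a
knockout sample) is reported as median 0 instead of an undefined ratio.

## Worked example

No real MaxQuant run is needed: the package ships a generator for
synthetic projects with planted ground truth.

```r
library(mqreport)

spec <- fixture_spec(
  n_proteins = 20, profiles = c(2, 1, 1, 1, 1, 1),   # channel 1 doubled
  replicates = c(raw1 = "R1"),
  nterm_sites = data.frame(position = c(1, 1, 2), prob = c(0.9, 0.9, 0.4)),
  n_oxidation_sites = 2, seed = 1)
fx <- generate_project(spec, "demo_project")

cfg <- load_reporting_config(fx$paths$config)
cfg$calibrate_channels <- FALSE   # the loading difference IS the signal here
run <- run_maxreport("demo_project", cfg, fx$paths$fasta, fx$paths$rule,
                     correction_matrix = fx$paths$correction_matrix)
print(run)
```

```
MaxQuant post-processing run
  protein groups: 20
  peptides: 62
  MS/MS scans: 602
  sites [Acetyl (Protein N-term)]: 3
  sites [Oxidation (M)]: 2
Libra quantification over 6 channels
  protein  20 entity(ies) quantified
  peptide  62 entity(ies) quantified
  site     4 entity(ies) quantified
  output: demo_project/maxreport
```

The decoy and contaminant groups planted by the generator are gone (20
groups reported), the three planted N-terminal acetylation sites were
recovered from `msms.txt`, and the quantification tables recover the
planted 2:1:1:1:1:1 profile — channel 1's median fraction is about twice
the others (2/7 ≈ 0.286 vs 1/7 ≈ 0.143):

```r
round(run$quant$protein$merged[1:3, 5:10], 3)
#>   Median Reporter 0 [R1] Median Reporter 1 [R1] Median Reporter 2 [R1]
#> 1                  0.278                  0.135                  0.145
#> 2                  0.280                  0.141                  0.143
#> 3                  0.281                  0.144                  0.146
#>   Median Reporter 3 [R1] Median Reporter 4 [R1] Median Reporter 5 [R1]
#> 1                  0.150                  0.139                  0.142
#> 2                  0.145                  0.140                  0.141
#> 3                  0.144                  0.136                  0.138

run$site_tables[["Acetyl (Protein N-term)"]][, c("Protein", "Position",
                                                 "Site class", "Sequence window")]
#>   Protein Position Site class Sequence window
#> 1 SYN0001        1   specific   ______MHACQTA
#> 2 SYN0002        1   specific   ______MDQATGN
#> 3 SYN0003        2  ambiguous   _____MHEYPENN
```

Sites at position 1 carry six `_` pads before the initiator residue; the
Met-cleaved site at position 2 shows the initiator Met as its first flank
residue. The site with localization probability 0.4 is classified
ambiguous (the specific class requires p > 0.5) and is therefore excluded
from site-level quantification.

`demo_project/maxreport/` now contains the minimized four-level tables,
site tables, quantification tables, statistics with SVG/TSV chart pairs, a
combined workbook (`combined_results.xml`, multi-sheet SpreadsheetML) and
`index.html` linking everything in six sections.

A command-line wrapper is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts", "mqreport", package = "mqreport"))')" \
  --project demo_project --fasta demo_project/sequences.fasta --rules uniprot
```

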