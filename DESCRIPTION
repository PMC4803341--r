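Package: mqreport
Title: Post-Processing, Site Reporting and Isobaric Quantification for
    MaxQuant Results
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reads a MaxQuant project directory ('combined/txt' tables),
    minimizes and annotates protein-group, peptide, site and MS/MS level
    identification tables, builds protein N-terminal modification site
    tables with sequence windows, performs Libra-style isobaric (TMT/iTRAQ)
    relative quantification with isotope-impurity correction, channel
    calibration, per-spectrum normalization and sigma-based outlier
    rejection, computes descriptive statistics, and writes an organized
    report bundle (TSV tables, SVG charts, a combined workbook and an HTML
    index). A synthetic-project generator with planted ground truth makes
    the whole pipeline testable without real instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    seqinr,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
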