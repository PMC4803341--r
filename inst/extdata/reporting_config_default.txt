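# mqreport reporting configuration (MaxQuant 1.5.x column dialect)
#
# [general] holds scalar settings; each logical table section lists one
# column-selection rule per line: "exact = <title>" or "keyword = <substring>".
[general]
ptm_names = Oxidation (M); Acetyl (Protein N-term)
flank_length = 6
loc_prob_threshold = 0.5
outlier_sigma = 1.96
low_intensity_threshold = 0
use_unique_peptides_only = true
ile_eq_leu = false
calibrate_channels = true

[protein_groups]
exact = Protein IDs
exact = Majority protein IDs
keyword = Peptide counts
exact = Peptides
exact = Unique peptides
exact = Score
keyword = Reporter intensity
exact = id
exact = MS/MS IDs

[peptides]
exact = Sequence
exact = Proteins
exact = Protein group IDs
exact = Unique (Groups)
exact = Score
exact = id
exact = MS/MS IDs

[sites]
exact = Proteins
exact = Protein
exact = Position
exact = Amino acid
exact = Localization prob
exact = Score
exact = Protein group IDs
exact = MS/MS IDs
exact = id

[msms]
exact = Raw file
exact = Scan number
exact = Sequence
exact = Modified sequence
exact = Modifications
exact = Proteins
exact = Protein group IDs
exact = Score
keyword = Reporter intensity
exact = Masses
exact = Matches
exact = Intensities
exact = id

[summary]
exact = Raw file
exact = Experiment
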