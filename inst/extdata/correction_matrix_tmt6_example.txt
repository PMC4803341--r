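# Example TMT6 isotope-impurity correction matrix (synthetic values in the
# typical range of vendor certificates; replace with the lot-specific sheet).
# Orientation: columns = true channel, rows = observed channel.
	TMT126	TMT127	TMT128	TMT129	TMT130	TMT131
TMT126	0.950	0.020	0.000	0.000	0.000	0.000
TMT127	0.040	0.945	0.025	0.001	0.000	0.000
TMT128	0.001	0.030	0.940	0.028	0.001	0.000
TMT129	0.000	0.001	0.030	0.935	0.030	0.002
TMT130	0.000	0.000	0.001	0.032	0.935	0.035
TMT131	0.000	0.000	0.000	0.001	0.030	0.930
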