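# Cohort simulation / analysis configuration.
# Omit `dataset` to simulate a cohort with the design fields below;
# set it to a dataset directory (data.csv + animals.csv) to analyze
# existing measurements.
# dataset: path/to/dataset
n_per_group_per_sex: 2
protocol: OGTT          # or MMTT
noise_cv_glucose: 0.03
noise_cv_enrichment: 0.02
noise_cv_insulin: 0.10
seed: 1
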