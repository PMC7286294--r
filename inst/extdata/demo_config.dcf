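master_seed: 1
cell_types: cholinergic, GABAergic, glutamatergic
stages: larva, adult
replicates: 3
reads_per_sample: 50000
chrom_length: 1500000
gatc_spacing: 250
n_genes: 80
beta: 1.0
dispersion: 0.2
n_unique_enriched: 8
n_unique_depleted: 4
permutations: 100
fdr_threshold: 0.01
min_score: 0.2
n_peaks: 8
peak_effect: 2.0
shuffles: 500
peak_fdr_threshold: 1e-4
window: 5000
delta: 10
k: 3
up: 5000
down: 2000
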