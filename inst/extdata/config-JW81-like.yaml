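# Primary/relapse pair with a de novo resistance mutation.
#
# The ancestral clone carries a heterozygous Notch1 mutation and dominates
# the primary tumor. At relapse a resistant clone absent from the primary
# (undetectable Pten mutation) takes over while the ancestral clone
# collapses, so Pten appears de novo near VAF 0.45 and Notch1 is depleted.
seed: 81
n_chromosomes: 19
chrom_length_bp: 1.0e8
snp_density: 1
mean_depth_normal: 120
mean_depth_tumor: 140
purity_primary: 0.98
purity_relapse: 0.98
target_mb: 50
bin_size_bp: 1.0e6
sites_per_bin: 50
error_rate: 0.001
overdispersion: 0
events: []
clones:
  - clone_id: ancestral
    fraction_primary: 0.97
    fraction_relapse: 0.05
    mutations:
      - {chrom: "2", pos: 26000000, gene: Notch1, multiplicity: 1}
  - clone_id: resistant
    fraction_primary: 0.0
    fraction_relapse: 0.92
    mutations:
      - {chrom: "19", pos: 33000000, gene: Pten, multiplicity: 1}
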