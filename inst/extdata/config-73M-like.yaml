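# Primary/relapse pair with a pre-existing resistant subclone.
#
# The ancestral clone carries a duplicated Kras mutation inside
# chromosome-6 copy-neutral LOH; a minor subclone carries the Kras mutation
# at single copy (heterozygous) plus a duplicated Pten mutation inside its
# own chromosome-19 CN-LOH. Under treatment the subclone expands, so the
# Kras VAF falls from ~0.92 towards ~0.55 (heterozygosity re-acquired at
# the population level) while the Pten VAF rises from ~0.11 to ~0.62.
seed: 73
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
events:
  - {chrom: "6", start: 1, end: 100000000, kind: CN_LOH, haplotype: S129,
     clone_ids: [ancestral]}
  - {chrom: "19", start: 1, end: 100000000, kind: CN_LOH, haplotype: S129,
     clone_ids: [resistant]}
clones:
  - clone_id: ancestral
    fraction_primary: 0.88
    fraction_relapse: 0.24
    mutations:
      - {chrom: "6", pos: 50000000, gene: Kras, multiplicity: 2}
  - clone_id: resistant
    fraction_primary: 0.11
    fraction_relapse: 0.63
    mutations:
      - {chrom: "6", pos: 50000000, gene: Kras, multiplicity: 1}
      - {chrom: "19", pos: 33000000, gene: Pten, multiplicity: 2}
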