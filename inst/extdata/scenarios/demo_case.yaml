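# Miniature four-sample metastatic case: one primary section and three
# metastases at purity 1 and 60x mean depth. Chromosome 1 carries
# trunk-level copy-loss LOH (before divergence), chromosome 2 copy-loss
# LOH private to metastasis M1, chromosome 3 retains heterozygosity.
case_id: DEMO
seed: 1
n_chromosomes: 3
chrom_length: 1000000
gc_content: 0.41
arm_fraction: 0.5
n_trunk_mutations: 300
n_private_mutations: 40
n_germline_snps: 120
samples:
  - {sample_id: P1, role: primary, purity: 1.0, mean_depth: 60}
  - {sample_id: M1, role: metastasis, purity: 1.0, mean_depth: 60}
  - {sample_id: M2, role: metastasis, purity: 1.0, mean_depth: 60}
  - {sample_id: M3, role: metastasis, purity: 1.0, mean_depth: 60}
truncal_loh:
  - {chrom: chr1, start: 0, end: 1000000, mode: copy_loss}
private_loh:
  - {chrom: chr2, start: 0, end: 1000000, mode: copy_loss, sample_id: M1}
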