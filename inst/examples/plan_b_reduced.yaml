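# Reduced-scale genomic-selection wheat plan (plan "B") for the breedsim CLI.
plan:
  strategy: GS        # PS | GS | SPB
  scale: 5            # 1 = full programme, 5 = reduced test scale
  corr_yp_ya: 0.3     # genetic correlation preliminary vs advanced yield
  corr_bvp: 0.0
  horizon: 25         # simulated years
  burn_in: 10         # last year of the phenotypic burn-in
# optional overrides:
# genome:
#   n_chrom: 1
#   lengths: 3.0
#   n_loci: 500
#   qtl_every_n: 10
#   n_ibd: 20
# founder:
#   n_pat: 100
#   n_mat: 100
#   ng_founder: 300
#   mutation_rate: 0.0025
#   culling_fraction: 0.05
run:
  replicates: 2
  seed: 1
  out: breedsim_out
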