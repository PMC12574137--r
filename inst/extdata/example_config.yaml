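# Example pipeline configuration: simulate a small synthetic cohort and run
# every downstream stage on it. Paths are resolved relative to the working
# directory; the gene_sets GMT ships with the package (see README).
seed: 7
outdir: premdd_out
n_probands: 1500
stages:
  simulate: true
  phenotypes: false
  associations: true
  milestones: true
  dnm: true
  enrichment: true
  scores: true
inputs:
  gene_sets: gene_sets.gmt
dnm_excess:
  ddg2p: 0.1
milestone_params:
  log_hr_by_category:
    moderate: -0.2
    very: -0.4
    extreme: -0.7
  log_hr_diagnosis: -0.5
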