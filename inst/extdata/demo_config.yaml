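# Demo configuration: a small two-condition degron depletion experiment.
# Two conditions (UHRF1-type: maintenance cofactor lost, de-novo enzymes
# strongly reduced, histone-coupled CGI demethylation; DNMT1-type:
# maintenance enzyme only), each sampled before (day0) and after (day4)
# depletion.
seed: 20260920
genome_length: 200000
n_contigs: 2
gc_content: 0.42
cgi_count: 60
cgi_length: 800
cgi_cpg_density: 0.08
enzyme_weights:
  dnmt1: 1.0
  dnmt3a: 0.8
  dnmt3b: 0.1
# bulk (context-free) logit contributions: depleting an enzyme lowers
# genome-wide methylation, so 1-kb tiles can cross the DMR thresholds.
# day0 level ~ logistic(-0.93 + 1.70 + 1.25 + 0.30) ~ 0.90; full DNMT1 loss
# alone brings tiles just past the 25-point threshold, UHRF1-type loss far past it.
enzyme_bulk:
  dnmt1: 1.70
  dnmt3a: 1.25
  dnmt3b: 0.30
symmetric_profiles: [dnmt3a, dnmt3b]
baseline: -0.93
site_noise_sd: 0.5
coverage_mean: 30
histone_coupling: 0.4
chip_depth: 400
conditions:
  UHRF1:
    day0: {coupled: false}
    day4:
      depletion: {dnmt1: 0.0, dnmt3a: 0.2, dnmt3b: 0.2}
      coupled: true
  DNMT1:
    day0: {coupled: false}
    day4:
      depletion: {dnmt1: 0.0}
      coupled: false
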