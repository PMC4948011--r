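# Per-dataset alignment filter policies, by query/target pair.
# Thresholds are stated in percent; synqtl stores them as fractions.
tocds_peg:
  min_identity: 80
  min_coverage: 75
  min_aligned_length: 200
  units: percent
pecds_tog:
  min_identity: 80
  min_coverage: 75
  min_aligned_length: 200
  units: percent
pem_peg:
  min_identity: 98
  min_match_bp: 200
  max_mismatch_bp: 50
  units: percent
egm_egg:
  min_identity: 75
  min_match_bp: 100
  max_mismatch_bp: 50
  units: percent
egm_tog:
  min_identity: 75
  min_coverage: 40
  min_aligned_length: 200
  units: percent
egm_peg:
  min_identity: 75
  min_coverage: 40
  min_aligned_length: 200
  units: percent
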