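seed: 3
stages:
  simulate: yes
  junctions: yes
  purity: yes
  offtarget: yes
reference:
  length: 100000
  gc: 0.41
  name: synthref
site:
  start: 50000
  length: 32
  strand: +
donor:
  cargo_size_bp: 1000
  end_len: 100
  backbone_len: 2000
  gc: 0.5
events:
  'n': 300
  offset_mode: 49
  offset_spread: 1.0
  p_trl: 0.95
  tsd_len: 5
  tsd_sub_rate: 0.004
  offtarget_rate: 0.0
amplicon:
  read_len: 150
  depth: 5
  unintegrated_fraction: 0.3
  indel_profile:
    rate: 0.02
    len_range:
    - 1
    - 3
    pos_sd: 5.0
  error_rate: 0.001
  junction_side: both
longread:
  n_events: 200
  simple_fraction: 0.9
  read_error: 0.005
  flank_len: 300
uditas:
  n_events: 1000
  offtarget_rate: 0.005
  umi_len: 12
  umis_per_event: 1
  reads_per_umi: 3
  flank_len: 40
  anchor_len: 20
junctions:
  anchor_len: 20
  max_edit: 2
  min_flank: 20
purity:
  window: 40
offtarget:
  merge_window: 5
  max_hamming: 1
  on_target_tol: 100
  flank_pad: 50
  n_shuffle: 1000
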