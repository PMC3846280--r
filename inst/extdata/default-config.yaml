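# Default detector configuration (mirrors plescout::default_config()).
repeats:
  min_unit: 50        # bp; pLTR units of interest are ~180-220 bp
  min_identity: 0.80  # diverged copies of one family still pair
  k: 12               # exact seed word, bp
  xdrop: 10           # extension stop: score drop below running maximum
tsd:
  min_len: 4
  max_len: 25
  max_mismatch: 0     # PLE TSDs are short exact duplications (8-10 bp)
  flank_probe: 60     # bp examined outside the element span
palindrome:
  min_len: 10
  max_mismatch: 2     # admits "nearly-perfect" long terminal palindromes
  max_spacer: 4
promoter:
  tata_motif: TATATATA
  inr_motif: TCACT    # reverse-orientation scans use ACATT
  max_spacing: 50
orf:
  min_aa: 300         # element ORFs run ~830-1300 aa
n_rich:
  window: 50
  threshold: 0.25
  min_len: 100        # documented inserts are 460-554 aa at 25-30% Asn
capture:
  min_identity: 0.80
  element_free_k: 20  # a cassette sharing no 20-mer with the ORF library is element-free
  min_anchor: 200
  flank_identity: 0.90
  motif_window: 50
classify:
  subfamily_cut: 0.10 # copies >= 90% identical share a subfamily
  family_cut: 0.25
  group_cut: 0.45
  anchor_k: 12
smallrna:
  max_mismatch: 1
  window: 100
  min_run: 3
boundary_slack: 2     # bp; tolerated difference between called and curated unit edges
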