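# Demo phantom layout: a unidirectional in-plane band (corpus-callosum-
# like), an in-plane crossing region (corona-radiata-like), and an
# inclined bundle (fornix-like).
shape: [24, 16]
regions:
- name: cc
  rows: [1, 8]
  cols: [1, 16]
  populations:
  - {phi: 90.0, alpha: 0.0, weight: 1.0}
- name: cr
  rows: [9, 16]
  cols: [1, 16]
  populations:
  - {phi: 30.0, alpha: 0.0, weight: 1.0}
  - {phi: 120.0, alpha: 0.0, weight: 1.0}
- name: f
  rows: [17, 24]
  cols: [1, 16]
  populations:
  - {phi: 60.0, alpha: 30.0, weight: 1.0}
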