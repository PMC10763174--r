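# Synthetic two-round panel mirroring the design shape of the motivating
# opioid-indicator e-Delphi study: 24 panellists over 20 items in round 1,
# expected 19 panellists over 20 + 13 items in round 2; 15 items built to
# be agreed-inappropriate and 5 to be agreed-equivocal.
n_panellists: 24
n_items: 20
n_modified: 13
attrition: 0.2083333
feedback_shift: 0.5
seed: 1
archetypes:
  - {kind: consensus, location: 2, dispersion: 1}
  - {kind: consensus, location: 2, dispersion: 1}
  - {kind: consensus, location: 2, dispersion: 1}
  - {kind: consensus, location: 2, dispersion: 1}
  - {kind: consensus, location: 2, dispersion: 1}
  - {kind: consensus, location: 2, dispersion: 1}
  - {kind: consensus, location: 2, dispersion: 1}
  - {kind: consensus, location: 2, dispersion: 1}
  - {kind: consensus, location: 2, dispersion: 1}
  - {kind: consensus, location: 2, dispersion: 1}
  - {kind: consensus, location: 2, dispersion: 1}
  - {kind: consensus, location: 2, dispersion: 1}
  - {kind: consensus, location: 2, dispersion: 1}
  - {kind: consensus, location: 2, dispersion: 1}
  - {kind: consensus, location: 2, dispersion: 1}
  - {kind: consensus, location: 5, dispersion: 1}
  - {kind: consensus, location: 5, dispersion: 1}
  - {kind: consensus, location: 5, dispersion: 1}
  - {kind: consensus, location: 5, dispersion: 1}
  - {kind: consensus, location: 5, dispersion: 1}
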