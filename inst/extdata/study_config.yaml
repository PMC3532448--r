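# Example stimulation-study configuration: large-field cell, 10 um disk
# electrode 40 um above the somatic plane, cathodic-first biphasic pulse.
cell:
  field_diameter: 191
  stratification_depth: 15
  seed: 1
  axon_extension: 900
electrode:
  radius: 10
  x: 50
  y: 0
  z: 40
pulse:
  amplitude: 1.5
  phase_ms: 0.1
  onset_ms: 1
scan:
  xlim: [-80, 200]
  ylim: [-60, 60]
  step: 20
  z: 40
search:
  tol: 0.1
  cap: 200
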