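# Frozen cross-field protocol for the desk-scale patch (64 mm, dx 0.5 mm).
#
# s1: stimuli as x-ranges (mm) at time t (ms); the default is a plane wave
#     launched from a 1.5 mm strip on the left edge.
# s2_time: lower-half cross-field stimulus (ms), timed into the
#     repolarization tail of the S1 wave so the broken front curls into a
#     rotor.  The timing window is narrow at this domain size; values were
#     established empirically per condition (normal tissue has ~2.3x longer
#     action potentials, pushing every landmark out).
common:
  size_mm: 64
  dx: 0.5
  dt: 0.025
  stim_amp: 60
caf:
  s1:
    - { t: 0, x: [0, 1.5] }
  s2_time: 170
normal:
  s1:
    - { t: 0, x: [0, 1.5] }
  s2_time: 340
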