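# Desk-scale configuration: 3 subjects generated directly at 128 Hz, the
# rLDA-FBCSP pipeline on a reduced grid, single selection mode. Finishes in
# minutes on one CPU.
protocol:
  n_subjects: 3
  channels: [F3, F4, C3, C4, P3, P4]
  fs: 128
  trial_dur: 4
  classes: [arriba, abajo, derecha, izquierda, adelante, atras]
  trials_per_class: 20
  task: words
model:
  background_exponent: 1
  snr: 1
  subject_gain_sd: 0.2
  seed: 1
families: [rlda]
grids:
  rlda:
    nsf: [2, 3]
    miql: [6]
    nof: [8, 10]
k: 4
modes: [intra]
seed: 1
preprocess:
  bandpass: [2, 40]
  target_fs: 128
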