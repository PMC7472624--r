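# Full-scale imagined-words study design: 15 subjects, 6-channel montage,
# 1024 Hz acquisition, 4 s trials, 40 imagined trials per class, 4-fold
# nested CV with both selection modes and all six decoder families at their
# default study grids. Expect a long runtime at this scale.
protocol:
  n_subjects: 15
  channels: [F3, F4, C3, C4, P3, P4]
  fs: 1024
  trial_dur: 4
  classes: [arriba, abajo, derecha, izquierda, adelante, atras]
  trials_per_class: 40
  task: words
model:
  background_exponent: 1
  snr: 1
  blink_rate: 1
  subject_gain_sd: 0.2
  seed: 1
families: [svm, rdf, rlda, shallow_cnn, deep_cnn, eegnet]
k: 4
modes: [intra, inter]
seed: 1
preprocess:
  bandpass: [2, 40]
  target_fs: 128
  blink_threshold: 0.8
  remove_blinks: true
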