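# Full-scale imagined-vowels design: as paper_words.yaml with the
# five-vowel class set.
protocol:
  n_subjects: 15
  channels: [F3, F4, C3, C4, P3, P4]
  fs: 1024
  trial_dur: 4
  classes: [a, e, i, o, u]
  trials_per_class: 40
  task: vowels
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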