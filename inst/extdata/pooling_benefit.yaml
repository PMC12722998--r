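# Desk-scale pooling-benefit experiment for `sonopool run`.
# Mirrors poolingBenefitConfig(): a single-frame baseline trained from
# scratch, then a 15-frame pooled model fine-tuned from its channel-inflated
# weights, evaluated on held-out subjects.
seed: 1
dataset:
  imageHeight: 64
  imageWidth: 64
  fps: 30
  durationS: 3
  fluidVisibilityFraction: 0.2
  nSubjects: 8
  videosPerSubject: 4
  positiveFraction: 0.5
models:
  single:
    windowSize: 1
    stride: 3
    train:
      maxEpochs: 50
      earlyStopPatience: 10
      init: kaiming_scratch
  pooled:
    windowSize: 15
    stride: 3
    initFrom: single
    train:
      maxEpochs: 12
      earlyStopPatience: 6
      init: pretrained_inflate
train:
  inputSize: 32
  batchSize: 32
  learningRate: 0.001
  splitFraction: 0.8
augment: {}
testSubjects: 3
thresholdCriterion: f1
compare:
- pooled
- single
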