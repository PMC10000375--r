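# Example retinopipe configuration (desk-scale profile).
# Any field omitted here falls back to defaultConfig("desk").
simulate:
  nPerClass: 30
  height: 64
  width: 64
  noiseDensity: 0.0
  illuminationStrength: 0.0
  blurSigma: 0.0
preprocess:
  denoise:
    enabled: true
    window: 5
    thresholdK: 6
  diffusion:
    enabled: true
    iters: 10
    dt: 0.2
    kappa: 0.1
  enhance:
    enabled: true
    PS: 15
    Tm: 50
hho:
  PS: 20
  Tm: 200
segment:
  MinPts: 5
  eps: 0.08
  extractionThreshold: 0.06
  maxSamples: 3000
  vesselnessThreshold: 0.08
ensemble:
  L: 3
  rFraction: 0.8
  scale: 0.125
  epochs: 15
  batchSize: 32
  lr: 0.001
  weighting: uniform
seed: 0
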