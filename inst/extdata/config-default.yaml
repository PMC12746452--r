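seed: 1
outdir: foldscape_run
nResidues: 76
helices:
  I:
  - 1
  - 27
  II:
  - 32
  - 47
  III:
  - 50
  - 69
apr:
- 42
- 48
generate:
  nFrames: 25
  jitterSigma: 0.015
  meltFraction: 0.3552632
descriptors:
  rmsdR0: 0.08
metad:
  height: 3.0
  sigma: 0.02
  gamma: 8.0
  pace: 100
  nSteps: 15000000
  exchangeStride: 2000
  recordStride: 100
  friction: 1.0
  dt: 0.002
ladder:
  tMin: 300.0
  tMax: 450.0
  nReplicas: 4
potential:
  form: double-funnel-2d
  x1: -0.8
  y1: 0.0
  d1: 18.0
  w1: 0.3
  x2: 0.8
  y2: 0.2
  d2: 15.0
  w2: 0.3
  kc: 25.0
fes:
  nbins: 28
  minDepth: 0.75
  maxEnergy: 5.0
  burnFraction: 0.5
path:
  from: 1
  to: 2
analysis:
  temperatures:
  - 300.0
  - 340.0
  - 380.0
  - 420.0
  - 450.0
  framesPerTemperature: 6
  sasaPoints: 240
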