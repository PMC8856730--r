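# Demonstration run: four simulated prophase-like conditions whose mean
# loop sizes mirror the wild-type / single-mutant / double-mutant ladder,
# analyzed end to end at 1 kb resolution.
mode: synthetic
outputDir: perimap-demo
resolution: 1000
seed: 1
genome:
  nChrom: 4
  chromLength: 700000
  centromereFraction: 0.3
features:
  borderOffset: 20000
  nArmSites: 1
  armSpacing: 30000
hic:
  depth: 5.0e6
  flankCentromere: 100000
  flankBorder: 25000
  conditions:
    - {id: wt,     loopSize: 10000, dotStrength: 4, seedOffset: 0}
    - {id: eco1,   loopSize: 20000, dotStrength: 4, seedOffset: 101}
    - {id: wpl1,   loopSize: 20000, dotStrength: 4, seedOffset: 202}
    - {id: double, loopSize: 40000, dotStrength: 4, seedOffset: 303}
chip:
  occupancy: 50
  ipEfficiency: 4
ratioPairs:
  - [eco1, wt]
  - [wpl1, wt]
  - [double, wt]
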