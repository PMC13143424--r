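# default desk-scale synthetic study conditions (see the methods vignette)
nChannels: 16
nSources: 6
rate: 32
duration: 2
bandAssignment: [delta, theta, alpha]
leadfieldDecay: 0.8
noiseExponent: 1
snrDb: 10
nWindows: 200
nClasses: 2
seed: 1
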