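# small synthetic barley-like MLG population, seed 42
G4G4G3G4G4G4G3G4G4G3G4G4G4G3G4G4G4G3G4G4G3G4G4G3G4G4G4G
G4G4G3G4G4G3G4G4G3G4G4G4G3G4G4G3G4G4G4G3G4G4G4G3G4G4G4G
G4G4G3G4G4G3G4G3G4G4G3G4G3G4G4G3G4G4G4G3G4G4G
G4G4G3G4G4G3G4G4G3G4G4G3G4G4G3G4G4G4G3G4G4G4G3G4G4G
G4G4G3G4G4G3G4G4G3G4G4G4G3G4G4G3G4G4G3G4G4G3G4G4G
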