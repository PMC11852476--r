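# Physiological joint-angle limits (degrees) used as the denominator of the
# range-of-motion joint weights.
shoulder_flexion: [0, 180]
elbow_flexion: [0, 150]
forearm_pronation: [-80, 80]
wrist_extension: [-70, 70]
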