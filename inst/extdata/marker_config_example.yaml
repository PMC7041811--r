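# Example marker configuration: anatomical role -> label used in the
# motion-capture export. Edit the right-hand side to match your lab's
# labelling scheme.
head_ref: Head_low
withers_mid: Withers_C
withers_left: Withers_L
withers_right: Withers_R
tuber_sacrale: TS
tuber_coxae_left: TC_L
tuber_coxae_right: TC_R
T12: T12
T15: T15
T18: T18
L3: L3
L5: L5
S5: S5
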