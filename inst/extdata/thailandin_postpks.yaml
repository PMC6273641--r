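# Post-PKS tailoring for the thailandin aglycone: thioesterase
# macrolactonization onto the most distal beta-hydroxyl, hemiketal
# (tetrahydropyran) closure of the retained keto group, and P450
# hydroxylation at C26. Rhamnosylation at C15 (giving the A-form) is
# applied separately.
macrolactonization: auto
hemiketal: auto
hydroxylations: [26]
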