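# Target-compound constraints for the thailandin B aglycone: a 28-membered
# macrocyclic lactone with two ring methyls, seven free hydroxyls, five
# conjugated double bonds, a C4 side chain at C2, and a reported mass of
# 608 g/mol. The C26 hydroxyl (a tailoring modification) is counted among
# the seven free hydroxyls.
name: thailandin B
ring_size: 28
hydroxyl_count: 7
conjugated_double_bonds: 5
methyl_count: 2
side_chain_position: 2
side_chain_length: 4
target_monoisotopic_mass: 608
backbone_carbons: 28
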