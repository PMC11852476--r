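# Correspondence between ability-database upper-limb tasks and the
# intervention's activities of daily living. Synthetic, movement-similarity
# based pairing; edit freely to match a site's own correspondence table.
towel_fold_toward: using two hands to move a towel
towel_fold_sideways: picking up a small block with two fingers
forward_reach: moving an object upwards to a cabinet
lateral_transfer: scanning goods
hand_to_mouth: performing an eating action
key_turn: pouring water into a cup
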