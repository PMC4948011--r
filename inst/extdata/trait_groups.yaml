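# Trait relatedness groups for cross-species QTL comparison. Two traits
# are treated as related when they appear in the same group.
- [fruit_weight, fruit_length, fruit_diameter, fruit_shape]
- [peduncle_length, flowering_time, fruit_number]
- [anthocyanin_fruit, anthocyanin_leaf, anthocyanin_stem]
- [plant_height, plant_width]
- [prickliness_leaf, prickliness_stem]
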