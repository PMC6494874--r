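# Traits for which larger measured values indicate LOWER fitness.
# Effect sizes for these traits have their sign inverted so that positive
# oriented effects always mean higher fitness under sexual selection.
# One label per line; matching is case-insensitive on the trait column.
parasite load
mutation load
extinction risk
extinction rate
mating latency
male mating latency
senescence
senescence rate
rate of senescence
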