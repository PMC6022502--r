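# SYNTHETIC example of a multi-lineage dog/wolf demography in the
# DomestiScan config format. The lineage structure mirrors the kind of
# history used for village-dog/wolf null models (regional dog lineages, a
# domestication bottleneck, wolf lineages, ancestral merges, a post-split
# admixture pulse), but every parameter value here is illustrative and
# NOT transcribed from any published model. Times are generations before
# present; sizes are diploid.
mutation_rate: 4.0e-9
generation_time: 3
recombination_rate: 1.0e-8
populations:
  - {name: dog, size: 13000}        # sampled village-dog lineage
  - {name: dog_east, size: 9000}
  - {name: wolf, size: 17000}       # sampled wolf lineage
  - {name: wolf_east, size: 11000}
events:
  # regional dog lineages merge
  - {time: 1500, type: pulse, pop: dog, dest: wolf, value: 0.02}
  - {time: 3000, type: merge, pop: dog_east, dest: dog}
  # domestication bottleneck on the dog stem
  - {time: 3000, type: size, pop: dog, value: 2500}
  # wolf lineages merge
  - {time: 3500, type: merge, pop: wolf_east, dest: wolf}
  # dog stem joins the wolf stem (domestication split, backward in time)
  - {time: 5000, type: merge, pop: dog, dest: wolf}
  - {time: 5000, type: size, pop: wolf, value: 32000}
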