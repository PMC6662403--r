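# Demo bundle configuration: six trait bundles in the style of European
# breeding-bird trait compilations (9/9/9/9/15/18 binary variables).
diet_year: [folivore, frugivore, granivore, arthropods, other_invertebrates,
            fish, other_vertebrates, carrion, omnivore]
diet_breeding: [folivore_b, frugivore_b, granivore_b, arthropods_b,
                other_invertebrates_b, fish_b, other_vertebrates_b,
                carrion_b, omnivore_b]
foraging_behavior: [pursuit, gleaning, pouncing, grazing, digging, probing,
                    scything, filtering, scavenging]
foraging_substrate: [water, mud, ground, vegetation, air, bark, walls,
                     snow, other_substrate]
habitat: [coast, wetland, river, grassland, heath, scrub, woodland_conifer,
          woodland_deciduous, woodland_mixed, farmland, orchard, parkland,
          urban, rocky, alpine]
nesting_site: [cliff, hole_tree, hole_bank, hole_building, ground_open,
               ground_cover, reedbed, bush_low, bush_high, tree_fork,
               tree_branch, tree_top, floating, burrow, ledge, roof,
               nest_parasite_host, other_site]
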