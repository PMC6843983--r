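code,category
1,other
2,other
3,other
4,other
5,other
6,other
7,coniferous_forest
8,coniferous_forest
9,dense_forest
10,dense_forest
11,dense_forest
12,fruit_trees
13,fruit_trees
14,artificial_vegetated
15,artificial_vegetated
16,transitional_scrub
17,transitional_scrub
18,natural_grassland
19,natural_grassland
20,mixed_forest
21,mixed_forest
22,mixed_forest
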