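"time_days","q_pct","sd_pct"
0.25,12.4919267681333,2
1,18.9843806037832,2
3,23.7745708511544,2
7,31.3427344445722,2
14,36.9120198785082,2
28,47.3420354793813,2
56,67.002321142962,2
84,75.2502115674268,2
112,80.709347511249,2
140,82.143742463047,2
180,86.4053001725254,2
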