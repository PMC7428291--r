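# 10-cube polycube layout, shape V (synthetic reconstruction).
# Flat chevron lying on the table.
# ix iy iz material
0 2 0 wood
1 2 0 wood
1 1 0 wood
2 1 0 wood
2 0 0 wood
3 0 0 wood
3 1 0 wood
4 1 0 wood
4 2 0 wood
5 2 0 wood
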