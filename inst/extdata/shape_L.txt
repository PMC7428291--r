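# 10-cube polycube layout, shape L (synthetic reconstruction; the published
# renderings constrain only the family, not the exact cube arrangement).
# Standing L: a 7-cube column with a 3-cube foot. One cube per line:
# ix iy iz material
0 0 0 wood
0 0 1 wood
0 0 2 wood
0 0 3 wood
0 0 4 wood
0 0 5 wood
0 0 6 wood
1 0 0 wood
2 0 0 wood
3 0 0 wood
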