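# Hairpin loop initiation penalties (kcal/mol, 37 C) by loop length.
# Loops longer than the last entry are extrapolated as
# dG(10) + 1.75 * R * T * ln(L / 10).
loop_length	delta_g
3	5.4
4	5.6
5	5.7
6	5.4
7	6.0
8	5.5
9	6.4
10	6.5
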