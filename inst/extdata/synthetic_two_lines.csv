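"concentration","effect","cell_line"
0.03333,0.06332,"lineA"
0.03333,0.04416,"lineA"
0.03333,0.03001,"lineA"
0.1036,0.08695,"lineA"
0.1036,0.14403,"lineA"
0.1036,0.11371,"lineA"
0.3218,0.23733,"lineA"
0.3218,0.18557,"lineA"
0.3218,0.19052,"lineA"
1,0.39538,"lineA"
1,0.5267,"lineA"
1,0.54828,"lineA"
3.107,0.74193,"lineA"
3.107,0.76365,"lineA"
3.107,0.73354,"lineA"
9.655,0.89494,"lineA"
9.655,0.86241,"lineA"
9.655,0.91307,"lineA"
30,0.95792,"lineA"
30,0.98986,"lineA"
30,0.97019,"lineA"
0.03333,0.12643,"lineB"
0.03333,0.04155,"lineB"
0.03333,0.09593,"lineB"
0.1036,0.18608,"lineB"
0.1036,0.24012,"lineB"
0.1036,0.23151,"lineB"
0.3218,0.44432,"lineB"
0.3218,0.54491,"lineB"
0.3218,0.4944,"lineB"
1,0.75193,"lineB"
1,0.79131,"lineB"
1,0.79504,"lineB"
3.107,0.89643,"lineB"
3.107,0.93705,"lineB"
3.107,0.91178,"lineB"
9.655,0.95725,"lineB"
9.655,0.98763,"lineB"
9.655,0.96688,"lineB"
30,0.99413,"lineB"
30,0.99665,"lineB"
30,0.99648,"lineB"
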