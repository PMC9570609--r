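"col","row"
9,5
9,6
8,3
8,4
8,5
8,6
8,7
8,8
8,9
10,3
10,4
10,5
10,6
10,7
10,8
10,9
7,4
7,5
7,6
7,7
7,8
11,4
11,5
11,6
11,7
11,8
6,5
6,6
12,5
12,6
5,4
5,5
5,6
5,7
5,8
5,9
4,5
4,6
4,7
4,8
3,6
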