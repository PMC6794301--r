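# 15-node, 19-edge worked example network (nodes A..O)
A E
A F
A G
B C
B D
B G
C G
C H
D G
E G
F G
F L
H I
H J
H K
I J
K M
K N
K O
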