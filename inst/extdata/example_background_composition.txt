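A 0.082574
C 0.013812
D 0.054549
E 0.067261
F 0.038635
G 0.070764
H 0.022720
I 0.059153
K 0.058052
L 0.096587
M 0.024122
N 0.040637
P 0.047443
Q 0.039335
R 0.055350
S 0.066560
T 0.053648
V 0.068562
W 0.011010
Y 0.029226
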