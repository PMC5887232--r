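# Seven-node worked example network, one phenotype node P.
#
# Transcription notes: the rules for P, C, E and A are stated directly
# in the source diagram's text.  The rules for B, D and F are read from
# the diagram and are pinned by independent dynamical facts of the same
# source: (i) the uncontrolled network has exactly the two point
# attractors (A,B,C,D,E,F,P) = (1,0,1,1,1,1,1) and (0,0,0,0,0,0,0);
# (ii) under the clamp {C=0} every initial state reaches the all-zero
# attractor, and under {B=1} every initial state reaches
# (0,1,0,0,0,0,0); (iii) exactly six single-node clamps force P = 0:
# {C=0}, {E=0}, {B=1}, {D=0}, {A=0}, {F=0}; (iv) A is the sole
# regulator of D and forms the last layer of the layered network for P.
targets, factors
A, F
B, C & !F
C, !B & D & E
D, A
E, D | F
F, C & D
P, C & E
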