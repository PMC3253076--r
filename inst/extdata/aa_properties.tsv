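residue	charge	polarity	polarity_volume
A	neutral	nonpolar	neutral-small
C	neutral	polar	special
D	negative	polar	polar-small
E	negative	polar	polar-small
F	neutral	nonpolar	nonpolar-large
G	neutral	polar	neutral-small
H	positive	polar	polar-large
I	neutral	nonpolar	nonpolar-small
K	positive	polar	polar-large
L	neutral	nonpolar	nonpolar-small
M	neutral	nonpolar	nonpolar-small
N	neutral	polar	polar-small
P	neutral	nonpolar	neutral-small
Q	neutral	polar	polar-small
R	positive	polar	polar-large
S	neutral	polar	neutral-small
T	neutral	polar	neutral-small
V	neutral	nonpolar	nonpolar-small
W	neutral	polar	nonpolar-large
Y	neutral	polar	nonpolar-large
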