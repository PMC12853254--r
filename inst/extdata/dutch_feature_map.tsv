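phoneme	voicing	manner	place	roundness	frontback
p	unvoiced	occlusive	labial	unrounded
b	voiced	occlusive	labial	unrounded
t	unvoiced	occlusive	coronal	unrounded
d	voiced	occlusive	coronal	unrounded
k	unvoiced	occlusive	velar	unrounded
g	voiced	occlusive	velar	unrounded
f	unvoiced	fricative	labial	unrounded
v	voiced	fricative	labial	unrounded
s	unvoiced	fricative	coronal	unrounded
z	voiced	fricative	coronal	unrounded
S	unvoiced	fricative	coronal	unrounded
Z	voiced	fricative	coronal	unrounded
x	unvoiced	fricative	velar	unrounded
G	voiced	fricative	velar	unrounded
h	unvoiced	fricative	glottal	unrounded
T	unvoiced	fricative	dental	unrounded
m	voiced	nasal	labial	unrounded
n	voiced	nasal	coronal	unrounded
N	voiced	nasal	velar	unrounded
l	voiced	approximant	coronal	unrounded
r	voiced	approximant	coronal	unrounded
j	voiced	approximant	coronal	unrounded
w	voiced	approximant	labial	rounded
I	voiced	short_vowel	high_vowel	unrounded	front
E	voiced	short_vowel	mid_vowel	unrounded	front
A	voiced	short_vowel	low_vowel	unrounded	central
O	voiced	short_vowel	mid_vowel	rounded	back
Y	voiced	short_vowel	mid_vowel	rounded	front
@	voiced	short_vowel	mid_vowel	unrounded	central
i	voiced	long_vowel	high_vowel	unrounded	front
y	voiced	long_vowel	high_vowel	rounded	front
u	voiced	long_vowel	high_vowel	rounded	back
e	voiced	long_vowel	mid_vowel	unrounded	front
2	voiced	long_vowel	mid_vowel	rounded	front
o	voiced	long_vowel	mid_vowel	rounded	back
a	voiced	long_vowel	low_vowel	unrounded	central
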