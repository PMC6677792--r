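# Monoisotopic masses (Da) of the most abundant isotope of each element.
# Values from the NIST/CODATA atomic mass evaluation; carbon is exactly 12 by
# definition of the unified atomic mass unit. Immutable at runtime.
# element	mass_da
H	1.00782503207
He	4.00260325415
Li	7.01600455
Be	9.0121822
B	11.0093054
C	12.0
N	14.0030740048
O	15.9949146196
F	18.99840322
Ne	19.9924401754
Na	22.9897692809
Mg	23.9850417
Al	26.98153863
Si	27.9769265325
P	30.97376163
S	31.97207100
Cl	34.96885268
Ar	39.9623831225
K	38.96370668
Ca	39.96259098
Ti	47.9479463
Cr	51.9405075
Mn	54.9380451
Fe	55.9349375
Co	58.9331950
Ni	57.9353429
Cu	62.9295975
Zn	63.9291422
Ga	68.9255736
Ge	73.9211778
As	74.9215965
Se	79.9165213
Br	78.9183371
Kr	83.911507
Rb	84.911789738
Sr	87.9056121
Mo	97.9054082
Ag	106.905097
Cd	113.9033585
Sn	119.9021947
Sb	120.9038157
Te	129.9062244
I	126.904473
Ba	137.9052472
W	183.9509312
Pt	194.9647911
Au	196.9665687
Hg	201.970643
Pb	207.9766521
Bi	208.9803987
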