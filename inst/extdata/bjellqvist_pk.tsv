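# Bjellqvist pK set (as used by the ExPASy Compute pI/Mw server), generic termini.
# Bjellqvist et al. (1993) Electrophoresis 14:1023-1031.
# type: nterm / cterm are the free termini; acid groups lose a proton, base groups gain one.
group	pk	type
nterm	7.50	base
cterm	3.55	acid
C	9.00	acid
D	4.05	acid
E	4.45	acid
H	5.98	base
K	10.00	base
R	12.00	base
Y	10.00	acid
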