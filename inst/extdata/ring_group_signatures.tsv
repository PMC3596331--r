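# Group-diagnostic features of the XB3-like C3HC4 RING domain.
# d67 = residues strictly between metal ligands 6 and 7; before_L8 = residue
# immediately preceding ligand 8 (comma-separated alternatives); before_L4
# applies to group II only ('-' = unconstrained).
# All groups additionally share: Pro right after ligand 7, Arg right after
# ligand 8, Val/Ile right before ligand 2.
group	d67_min	d67_max	before_L8	before_L4
I	19	23	L	-
II	21	24	F	G
III	11	11	V,I	-
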