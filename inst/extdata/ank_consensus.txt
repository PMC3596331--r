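# Packaged 33-residue ankyrin repeat consensus, after the designed consensus of
# Mosavi et al. (2002) PNAS 99:16029-16034 (TPLHxAA ... GADVNA hallmarks),
# with degenerate positions instantiated by common natural residues.
# Contains no cysteine, so ANK arrays never mimic RING metal ligands.
DKSGKTPLHLAAREGHLEIVEVLLKAGADVNAK
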