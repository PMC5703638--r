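# Quoted atom number densities (atoms/nm^3) for the reference materials,
# as tabulated. These are the canonical inputs of the calibration chain.
# Note: the quoted rRNA Mg value (0.24) is not reproducible from the rRNA
# atom count and PSV, which give 0.109; it contributes ~0.2% of the rRNA
# scattering signal, so downstream quantities are unaffected at quoted
# precision.
material,element,atoms_per_nm3
rRNA,C,31.2
rRNA,H,35.5
rRNA,N,12.7
rRNA,O,22.9
rRNA,P,3.3
rRNA,Mg,0.24
ribosome,C,19.3
ribosome,H,53.2
ribosome,N,6.86
ribosome,O,23.0
ribosome,S,0.072
ribosome,P,1.03
ribosome,Mg,0.034
TCP,Ca,18.4
TCP,P,12.2
TCP,O,49.1
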