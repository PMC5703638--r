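# Atom counts for the packaged reference materials.
# rRNA: ribosomal RNA component; densities derive via PSV 0.569 cm^3/g.
# ribosome: full solvated particle over a 7000 nm^3 envelope (counts
#   include the 42% bulk-solvent water inside the isosurface).
material,element,count
rRNA,C,68671
rRNA,H,78158
rRNA,N,27884
rRNA,O,50462
rRNA,P,7216
rRNA,Mg,239
ribosome,C,135061
ribosome,H,372416
ribosome,N,48041
ribosome,O,161037
ribosome,S,501
ribosome,P,7216
ribosome,Mg,239
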