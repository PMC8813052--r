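name	length	description
WT	297	Wild-type Drosophila Cdt1 N-terminal IDR (residues 1-297)
PheToLeu	297	All 8 Phe of the Cdt1 IDR replaced by Leu (aromaticity removed, hydrophobicity kept)
PheToAla	297	All 8 Phe of the Cdt1 IDR replaced by Ala
Uniform	297	Charged residues (K,R,D,E) redistributed evenly across the IDR (low kappa), composition otherwise as WT
Del1_100	198	Cdt1 IDR with residues 1-100 deleted; initiator Met prepended
Del101_200	197	Cdt1 IDR with residues 101-200 deleted
Del201_297	200	Cdt1 IDR with residues 201-297 deleted
DelCoiledCoil	269	Cdt1 IDR with the predicted coiled-coil (residues 196-223) deleted
ScrIDR	297	Random permutation of the WT Cdt1 IDR (composition-preserving sequence-order null)
IleLeu05	297	Half of all Ile and Leu of the Cdt1 IDR replaced by Ala
IleLeu10	297	All Ile and Leu of the Cdt1 IDR replaced by Ala
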