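# Physicochemical properties of the 20 standard amino acids.
# vdw_volume: residue Van der Waals volume, A^3 (Zamyatnin-style residue
#   volume scale; Gln follows the 143.9 A^3 value used alongside Ala 88.6,
#   Phe 189.9 and Trp 227.8 in the nanopore-clogging literature).
# apparent_volume: apparent (mean solution) residue volume, A^3 -- compiled
#   approximation from standard mean-residue-volume scales; values are
#   approximate stand-ins for the original apparent-volume measurements.
# asa: theoretical maximum solvent-accessible surface area of the residue
#   in a Gly-X-Gly tripeptide, A^2 (Tien et al. 2013).
# hclass: HYDROPHOBIC / POLAR / POSITIVE / NEGATIVE (His is classed POLAR
#   by default; see aa_lookup(positive_his = TRUE)).
code	name	name3	vdw_volume	apparent_volume	asa	hclass
A	Alanine	ALA	88.6	90.1	129	HYDROPHOBIC
R	Arginine	ARG	173.4	192.8	274	POSITIVE
N	Asparagine	ASN	114.1	127.5	195	POLAR
D	Aspartate	ASP	111.1	117.1	193	NEGATIVE
C	Cysteine	CYS	108.5	113.2	167	HYDROPHOBIC
Q	Glutamine	GLN	143.9	149.4	225	POLAR
E	Glutamate	GLU	138.4	140.8	223	NEGATIVE
G	Glycine	GLY	60.1	63.8	104	HYDROPHOBIC
H	Histidine	HIS	153.2	159.3	224	POLAR
I	Isoleucine	ILE	166.7	164.9	197	HYDROPHOBIC
L	Leucine	LEU	166.7	164.6	201	HYDROPHOBIC
K	Lysine	LYS	168.6	170.0	236	POSITIVE
M	Methionine	MET	162.9	167.7	224	HYDROPHOBIC
F	Phenylalanine	PHE	189.9	191.9	240	HYDROPHOBIC
P	Proline	PRO	112.7	123.3	159	HYDROPHOBIC
S	Serine	SER	89.0	94.2	155	POLAR
T	Threonine	THR	116.1	120.0	172	POLAR
W	Tryptophan	TRP	227.8	228.5	285	HYDROPHOBIC
Y	Tyrosine	TYR	193.6	197.1	263	POLAR
V	Valine	VAL	140.0	139.1	174	HYDROPHOBIC
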