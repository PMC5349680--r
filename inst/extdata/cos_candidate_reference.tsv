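protein_id	mass_kda	empai_cos	empai_cis	share_printed	annotation_class
creatine kinase b-type	16	1.92	0	1	known_elsewhere
ADP-ribosylation factor 1	21	1.34	0	1	unassigned
protein RD3	15	1.04	0	1	known_elsewhere
retinoschisin precursor	22	0.62	0	1	known_elsewhere
guanine nucleotide-binding protein G(i) subunit alpha-1	40	0.56	0	1	unassigned
guanine nucleotide-binding protein subunit alpha-13-like	34	0.52	0	1	unassigned
gamma-glutamyltransferase 5 isoform X1	62	0.5	0	1	unassigned
cyclic nucleotide-gated cation channel beta-3-like isoform X2	28	0.47	0	1	known_cos_specific
carbonic anhydrase	29	0.45	0	1	known_elsewhere
cadherin-related family member 5-like isoform X2	20	0.41	0	1	unassigned
neurocalcin-delta B	22	0.38	0	1	unassigned
cyclic nucleotide-gated channel cone photoreceptor subunit alpha isoform X2	81	0.36	0	1	known_cos_specific
flotillin 1a isoform X1	47	0.35	0	1	unassigned
ras-related protein Rab-43	23	0.35	0	1	unassigned
vitamin K epoxide reductase complex subunit 1-like protein 1	12	0.34	0	1	known_elsewhere
ras-related protein Rab-35-like	24	0.34	0	1	unassigned
Fc receptor-like protein 5 isoform X2	12	0.33	0	1	unassigned
SH3-containing GRB2-like protein 3-interacting protein 1 isoform X2	12	0.32	0	1	unassigned
synaptic vesicle glycoprotein 2B	12	0.32	0	1	unassigned
uncharacterized protein LOC100334801 isoform X2	26	0.31	0	1	unassigned
guanine nucleotide-binding protein G(i) subunit alpha-2	41	0.3	0	1	unassigned
ubiquitin-like 3b	13	0.3	0	1	unassigned
ras-related GTP-binding protein C	13	0.29	0	1	unassigned
band 3 anion transport protein (211V-519E)	35	3.68	0.08	0.98	known_elsewhere
cyclic nucleotide-gated channel rod photoreceptor subunit alpha-like	82	0.56	0.02	0.974	known_elsewhere
ammonium transporter Rh type A isoform X1	12	3.2	0.11	0.967	known_elsewhere
flotillin-1	41	2.14	0.1	0.955	unassigned
band 3 anion transport protein (92M-191C)	11	5.06	0.27	0.949	known_elsewhere
flotillin-2a	47	2.12	0.12	0.947	unassigned
guanine nucleotide-binding protein G(t) subunit alpha-2	40	28.3	2.02	0.933	known_cos_specific
opsin-1, short-wave-sensitive 1	39	0.44	0.03	0.933	known_cos_specific
band 3 anion transport protein (562G-810W)	27	1.17	0.1	0.923	known_elsewhere
regulator of G-protein signaling 9-binding protein-like	27	6.33	0.63	0.909	known_elsewhere
signal peptidase complex subunit 3	20	1.39	0.14	0.909	known_elsewhere
metal transporter CNNM4	35	0.66	0.08	0.898	known_elsewhere
brain creatine kinase b	43	0.52	0.06	0.895	known_elsewhere
adipocyte plasma membrane-associated protein	47	1	0.12	0.893	unassigned
green-sensitive opsin-4	39	2.04	0.25	0.892	known_cos_specific
regulator of G-protein signaling 9 isoform X2	62	0.9	0.11	0.889	known_elsewhere
guanine nucleotide-binding protein G(o) subunit alpha	40	1.44	0.19	0.885	unassigned
protein kinase, cAMP-dependent, regulatory, type II, alpha A	45	0.62	0.09	0.872	unassigned
synaptotagmin II	47	0.36	0.06	0.867	unassigned
G-protein-coupled receptor kinase 7A	62	3.49	0.56	0.863	known_cos_specific
dolichyl-diphosphooligosaccharide--protein glycosyltransferase 48 kDa subunit precursor	51	0.63	0.11	0.854	known_elsewhere
solute carrier family 2, facilitated glucose transporter member 1	53	0.61	0.1	0.854	unassigned
peroxiredoxin-2	22	0.62	0.13	0.831	unassigned
sodium/potassium/calcium exchanger 2-like isoform X2	68	0.45	0.1	0.816	known_cos_specific
cone cGMP-specific 3',5'-cyclic phosphodiesterase subunit alpha'	98	0.39	0.1	0.8	known_cos_specific
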