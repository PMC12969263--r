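# Side-chain (lambda/rho) log10 multiplicative factors for base-catalysed
# backbone-amide hydrogen exchange, relative to the poly-DL-alanine (PDLA)
# reference state (alanine = 0 by definition).
# Source: Bai, Milne, Mayne & Englander (1993) Proteins 17, 75-86, Table 2
# (base-catalysis columns). Table version: bai1993-base-v1.
# Conventions:
#   log_B_lambda(X) = effect of residue X when it is the LEFT neighbour of
#                     an amide (i.e. on the amide of the following residue);
#   log_B_rho(X)    = effect of residue X on its OWN backbone amide.
#   The amide of residue i therefore uses lambda(residue i-1) + rho(residue i).
#   N_TERM: extra lambda-type term on the amide of residue 2 (free alpha-amine).
#   C_TERM: extra rho-type term on the amide of the C-terminal residue
#           (carboxylate form).
#   P (proline, trans) has no amide hydrogen: rho is NA, lambda applies when
#   proline is the left neighbour.
# Reference-condition protonation states at near-neutral pL: Asp and Glu as
# carboxylates, Lys/Arg protonated, His neutral, Cys reduced.
# medium: H_base = abstraction by OH-, D_base = abstraction by OD-. The
# published factors do not resolve the abstracting isotope; the same values
# are used for both media (they cancel in the fractionation-factor ratio).
residue_code	log_B_lambda	log_B_rho	medium	notes
A	0.00	0.00	H_base	
R	0.22	0.08	H_base	
N	0.32	0.49	H_base	
D	-0.18	0.10	H_base	
C	0.55	0.62	H_base	
E	-0.15	-0.11	H_base	
Q	0.20	0.06	H_base	
G	0.17	0.27	H_base	
H	0.14	-0.10	H_base	
I	-0.23	-0.73	H_base	
L	-0.21	-0.58	H_base	
K	0.12	-0.04	H_base	
M	0.11	-0.01	H_base	
F	0.06	-0.24	H_base	
P	-0.24	NA	H_base	
S	0.30	0.37	H_base	
T	0.20	-0.07	H_base	
W	-0.11	-0.41	H_base	
Y	0.05	-0.27	H_base	
V	-0.14	-0.70	H_base	
N_TERM	1.62	NA	H_base	
C_TERM	NA	-1.80	H_base	
A	0.00	0.00	D_base	
R	0.22	0.08	D_base	
N	0.32	0.49	D_base	
D	-0.18	0.10	D_base	
C	0.55	0.62	D_base	
E	-0.15	-0.11	D_base	
Q	0.20	0.06	D_base	
G	0.17	0.27	D_base	
H	0.14	-0.10	D_base	
I	-0.23	-0.73	D_base	
L	-0.21	-0.58	D_base	
K	0.12	-0.04	D_base	
M	0.11	-0.01	D_base	
F	0.06	-0.24	D_base	
P	-0.24	NA	D_base	
S	0.30	0.37	D_base	
T	0.20	-0.07	D_base	
W	-0.11	-0.41	D_base	
Y	0.05	-0.27	D_base	
V	-0.14	-0.70	D_base	
N_TERM	1.62	NA	D_base	
C_TERM	NA	-1.80	D_base	
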