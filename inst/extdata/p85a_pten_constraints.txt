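# Default declarative constraints for auditing candidate models of the
# homodimeric p85a (chains A, B) : PTEN (chain P) assembly. Residue numbers
# follow author numbering of the p85a (PIK3R1) and PTEN sequences.
# User-extensible: one constraint per line, see read_constraints().

# BH:BH homodimer contacts centred on M176 inserting into the partner's
# hydrophobic pocket (L164', I177', V181')
contact A:176 B:164 5.5   # M176 against L164' pocket wall
contact A:176 B:177 5.5   # M176 against I177' pocket wall
contact A:176 B:181 5.5   # M176 against V181' pocket wall
symmetric A B 1.0         # BH:BH homodimer is two-fold symmetric

# PTEN phosphatase domain binds the BH surface carrying I127/I133/E137
interface_contains A P A:127,A:133,A:137   # proposed PTEN-binding surface

# Complexation renders the PTEN ubiquitination site K13 inaccessible
buried P:13 0.15

# p85a W298 (start of flexible PR2) lies near the bound PTEN
contact A:298 P:14 12.0   # PR2 anchor within reach of the PTEN N-terminus

# PTEN-binding surface and the small-GTPase site on BH are disjoint
# (binding is non-competitive)
disjoint_interfaces A:127,A:133,A:137 A:151,A:193,A:205
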