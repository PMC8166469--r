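symbol	category
CXCL14	Antimicrobials
CXCL14	Chemokines
CXCL14	Cytokines
BST2	Antimicrobials
RBP1	Antimicrobials
STC2	Cytokines
RBP7	Antimicrobials
PTGS2	Antimicrobials
ARG2	Antimicrobials
APOD	Antimicrobials
IL17RB	Cytokine_receptors
IL17RB	Interleukins_receptor
GNAI1	Antimicrobials
GRP	Cytokines
CCL4	Antimicrobials
CCL4	Chemokines
CCL4	Cytokines
INHBB	Cytokines
INHBB	TGFb_family_member
ABCC4	Antimicrobials
CCR7	Antimicrobials
CCR7	Chemokine_receptors
CCR7	Cytokine_receptors
CD86	Antimicrobials
IL7	Cytokines
C5AR1	Chemokine_receptors
C5AR1	Cytokine_receptors
NR3C2	Cytokine_receptors
PDGFC	Cytokines
HNF4G	Cytokine_receptors
IL10RA	Cytokine_receptors
IL10RA	Interleukins_receptor
TNFRSF11A	Cytokine_receptors
TNFRSF11A	TNF_family_members_receptors
RORC	Cytokine_receptors
PRKCQ	TCR_signaling_pathway
LCK	Natural_killer_cell_cytotoxicity
LCK	TCR_signaling_pathway
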