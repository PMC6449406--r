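protein	cloned	purified	experimental_group	pcpe_control	folch	ptdins3p	ptdins4p	ptdins5p	ptdins34p2	ptdins35p2	ptdins45p2	ptdins345p3	ps	encoding_note
SNX1	TRUE	TRUE	III	FALSE	TRUE	FALSE	FALSE	FALSE	TRUE	FALSE	FALSE	FALSE	FALSE	pelleting lanes: Folch and PtdIns(3,4)P2 only
SNX2	TRUE	TRUE	III	FALSE	TRUE	FALSE	FALSE	FALSE	TRUE	FALSE	FALSE	FALSE	FALSE	pelleting lanes: Folch and PtdIns(3,4)P2 only
SNX3	TRUE	TRUE	II	FALSE	FALSE	TRUE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	named PtdIns3P-exclusive in the screen
SNX4	TRUE	TRUE	IV	FALSE	TRUE	TRUE	FALSE	FALSE	FALSE	FALSE	TRUE	FALSE	FALSE	curator encoding from the screen summary
SNX5	TRUE	TRUE	I	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	named nonbinder in the screen
SNX6	TRUE	TRUE	I	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	named nonbinder in the screen
SNX7	TRUE	TRUE	II	FALSE	FALSE	TRUE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	named PtdIns3P-exclusive in the screen
SNX8	TRUE	FALSE	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	not purified; predicted group II from sequence
SNX9	TRUE	TRUE	IV	FALSE	TRUE	TRUE	FALSE	FALSE	FALSE	FALSE	TRUE	TRUE	FALSE	curator encoding from the screen summary
SNX10	TRUE	TRUE	II	FALSE	FALSE	TRUE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	curator judgement to match the stated Group II tally of 12
SNX11	TRUE	TRUE	II	FALSE	FALSE	TRUE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	slight PtdIns3P preference; curator-encoded exclusive (Group II tally)
SNX12	TRUE	TRUE	II	FALSE	FALSE	TRUE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	slight PtdIns3P preference; curator-encoded exclusive (Group II tally)
SNX13	TRUE	TRUE	II	FALSE	FALSE	TRUE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	PtdIns3P preference restated in the screen
SNX14	TRUE	TRUE	I	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	named nonbinder in the screen
SNX15	TRUE	TRUE	IV	FALSE	TRUE	TRUE	FALSE	FALSE	TRUE	TRUE	TRUE	FALSE	FALSE	domain-swapped dimer; binds PtdIns3P and PIP2 species
SNX16	TRUE	TRUE	II	FALSE	FALSE	TRUE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	named PtdIns3P-exclusive in the screen
SNX17	TRUE	TRUE	II	FALSE	FALSE	TRUE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	named PtdIns3P-exclusive in the screen; known-exception (secondary site present)
SNX18	TRUE	TRUE	IV	FALSE	TRUE	TRUE	FALSE	FALSE	FALSE	FALSE	TRUE	FALSE	FALSE	curator encoding from the screen summary
SNX19	TRUE	TRUE	II	FALSE	FALSE	TRUE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	named PtdIns3P-exclusive in the screen
SNX20	TRUE	TRUE	I	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	curator encoding from the screen summary
SNX21	TRUE	TRUE	I	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	curator encoding from the screen summary
SNX22	TRUE	TRUE	III	FALSE	TRUE	FALSE	FALSE	FALSE	TRUE	FALSE	FALSE	TRUE	FALSE	noted PtdIns(3,4)P2 preference
SNX23	TRUE	TRUE	IV	FALSE	TRUE	TRUE	FALSE	FALSE	TRUE	FALSE	FALSE	TRUE	FALSE	group IV in the mutagenesis experiments
SNX24	TRUE	TRUE	IV	FALSE	TRUE	TRUE	FALSE	FALSE	TRUE	FALSE	FALSE	FALSE	FALSE	group IV in the mutagenesis experiments
SNX25	TRUE	TRUE	III	FALSE	TRUE	FALSE	FALSE	FALSE	TRUE	TRUE	TRUE	TRUE	FALSE	NMR titrations: PIP2 and PIP3 species only, no PtdIns3P or PtdIns4P
SNX26	TRUE	FALSE	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	not purified; curator choice of the 7 failed purifications
SNX27	TRUE	TRUE	II	FALSE	TRUE	TRUE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	PtdIns3P-specific with weak Folch binding noted; known-exception
SNX29	TRUE	FALSE	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	not purified; curator choice of the 7 failed purifications
SNX30	TRUE	FALSE	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	not purified; predicted group II from sequence
SNX31	TRUE	FALSE	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	not purified; curator choice of the 7 failed purifications
SNX32	TRUE	TRUE	I	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	named nonbinder in the screen
SNX33	TRUE	TRUE	I	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	curator encoding from the screen summary
p40phox	TRUE	TRUE	II	FALSE	FALSE	TRUE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	named PtdIns3P-exclusive in the screen
p47phox	TRUE	TRUE	IV	FALSE	TRUE	TRUE	FALSE	FALSE	TRUE	FALSE	FALSE	FALSE	TRUE	group IV; canonical-site R44A blocks PtdIns3P but retains Folch/other binding
PXK	TRUE	TRUE	II	FALSE	FALSE	TRUE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	named PtdIns3P-exclusive in the screen
SGK3	TRUE	TRUE	IV	FALSE	TRUE	TRUE	FALSE	FALSE	TRUE	FALSE	FALSE	TRUE	FALSE	group IV; used in the two-ligand competition experiments
PI3KC2A	TRUE	TRUE	III	FALSE	TRUE	FALSE	FALSE	FALSE	TRUE	TRUE	TRUE	TRUE	FALSE	di/tri-phosphorylated species with similar affinity, no restricted specificity
PI3KC2B	TRUE	TRUE	III	FALSE	TRUE	FALSE	FALSE	FALSE	TRUE	FALSE	TRUE	TRUE	FALSE	curator encoding from the screen summary
PI3KC2G	FALSE	FALSE	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	not cloned; curator choice of the 3 uncloned records
PLD1	FALSE	FALSE	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	not cloned; predicted group III from sequence
PLD2	FALSE	FALSE	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	not cloned; predicted group III from sequence
SH3PXD2A	TRUE	TRUE	III	FALSE	TRUE	FALSE	FALSE	FALSE	TRUE	FALSE	FALSE	TRUE	TRUE	assayed with GST-tag intact; curator encoding
SH3PXD2B	TRUE	TRUE	III	FALSE	TRUE	FALSE	FALSE	FALSE	TRUE	FALSE	TRUE	FALSE	FALSE	curator encoding from the screen summary
HS1BP3	TRUE	TRUE	I	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	curator encoding from the screen summary
NOXO1	TRUE	TRUE	III	FALSE	TRUE	FALSE	TRUE	TRUE	FALSE	FALSE	FALSE	FALSE	TRUE	curator encoding from the screen summary
RPS6KC1	TRUE	TRUE	I	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	curator encoding from the screen summary
RPS6KL1	TRUE	FALSE	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	not purified; curator choice of the 7 failed purifications
NISCH	TRUE	FALSE	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	not purified; curator choice of the 7 failed purifications
PXDC1	TRUE	TRUE	I	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	curator encoding from the screen summary
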