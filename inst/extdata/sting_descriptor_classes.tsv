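pattern	abbrev	parent_class
entropy_density	ED	Entropy density
contact_energy_density	CED	Contact energy density
weighted_contact_number	WCN	Weighted contact number
cross_link_order	CLO	Cross link order
cross_presence_order	CPO	Cross presence order
residue_contacts	RC	Residue contacts
unused_contacts	UC	Unused contacts
side_chain_(angle|orientation)	SCO	Side chain orientation
electrostatic_potential	EP	Electrostatic potential
graph_descriptor	GD	Graph descriptor
curvature	Curv	Curvature
density	Density	Density
solvation	Solv	Solvation
sponge	Sponge	Sponge
accessibility	Accessibility	Accessibility
hydrophobicity	Hydrophobicity	Hydrophobicity
dssp	DSSP	DSSP
stride	STRIDE	STRIDE
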