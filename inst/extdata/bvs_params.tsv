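# Bond-valence parameters for Mn-ligand bonds.
# External reference data (published compilations), shipped for convenience
# and editable by the user; not derived in this package.
# R0 and B in Angstrom. Sources: Brese & O'Keeffe, Acta Cryst. B47 (1991)
# 192-197; I. D. Brown, accumulated bond-valence parameter tables.
state	element	R0	B	source
II	O	1.790	0.37	Brese & O'Keeffe 1991
III	O	1.760	0.37	Brese & O'Keeffe 1991
IV	O	1.753	0.37	Brese & O'Keeffe 1991
II	N	1.849	0.37	Brese & O'Keeffe 1991
III	N	1.837	0.37	Brown parameter tables
IV	N	1.822	0.37	Brown parameter tables
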