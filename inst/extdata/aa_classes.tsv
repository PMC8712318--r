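# Amino-acid physicochemical class assignments.
# acidity_polarity: classic four-way acidity/polarity partition.
# Remaining schemes follow the IMGT amino-acid classification
# (hydropathy, volume in cubic Angstrom bins, chemical group, charge,
# hydrogen-bond donor/acceptor atoms, polarity).
scheme	class	aa
acidity_polarity	neutral_apolar	G
acidity_polarity	neutral_apolar	A
acidity_polarity	neutral_apolar	V
acidity_polarity	neutral_apolar	L
acidity_polarity	neutral_apolar	I
acidity_polarity	neutral_apolar	P
acidity_polarity	neutral_apolar	F
acidity_polarity	neutral_apolar	M
acidity_polarity	neutral_apolar	W
acidity_polarity	neutral_polar	S
acidity_polarity	neutral_polar	T
acidity_polarity	neutral_polar	C
acidity_polarity	neutral_polar	Y
acidity_polarity	neutral_polar	N
acidity_polarity	neutral_polar	Q
acidity_polarity	acidic	D
acidity_polarity	acidic	E
acidity_polarity	basic	K
acidity_polarity	basic	R
acidity_polarity	basic	H
hydropathy	hydrophobic	A
hydropathy	hydrophobic	C
hydropathy	hydrophobic	I
hydropathy	hydrophobic	L
hydropathy	hydrophobic	M
hydropathy	hydrophobic	F
hydropathy	hydrophobic	W
hydropathy	hydrophobic	V
hydropathy	neutral	G
hydropathy	neutral	H
hydropathy	neutral	P
hydropathy	neutral	S
hydropathy	neutral	T
hydropathy	neutral	Y
hydropathy	hydrophilic	R
hydropathy	hydrophilic	N
hydropathy	hydrophilic	D
hydropathy	hydrophilic	Q
hydropathy	hydrophilic	E
hydropathy	hydrophilic	K
volume	very_small	A
volume	very_small	G
volume	very_small	S
volume	small	N
volume	small	D
volume	small	C
volume	small	P
volume	small	T
volume	medium	Q
volume	medium	E
volume	medium	H
volume	medium	V
volume	large	R
volume	large	I
volume	large	L
volume	large	K
volume	large	M
volume	very_large	F
volume	very_large	W
volume	very_large	Y
chemical	aliphatic	A
chemical	aliphatic	G
chemical	aliphatic	I
chemical	aliphatic	L
chemical	aliphatic	P
chemical	aliphatic	V
chemical	aromatic	F
chemical	aromatic	W
chemical	aromatic	Y
chemical	sulfur	C
chemical	sulfur	M
chemical	hydroxyl	S
chemical	hydroxyl	T
chemical	basic	R
chemical	basic	H
chemical	basic	K
chemical	acidic	D
chemical	acidic	E
chemical	amide	N
chemical	amide	Q
charge	positive	R
charge	positive	H
charge	positive	K
charge	negative	D
charge	negative	E
charge	uncharged	A
charge	uncharged	N
charge	uncharged	C
charge	uncharged	Q
charge	uncharged	G
charge	uncharged	I
charge	uncharged	L
charge	uncharged	M
charge	uncharged	F
charge	uncharged	P
charge	uncharged	S
charge	uncharged	T
charge	uncharged	W
charge	uncharged	Y
charge	uncharged	V
hydrogen_bond	donor	R
hydrogen_bond	donor	K
hydrogen_bond	donor	W
hydrogen_bond	donor_acceptor	H
hydrogen_bond	donor_acceptor	N
hydrogen_bond	donor_acceptor	Q
hydrogen_bond	donor_acceptor	S
hydrogen_bond	donor_acceptor	T
hydrogen_bond	donor_acceptor	Y
hydrogen_bond	acceptor	D
hydrogen_bond	acceptor	E
hydrogen_bond	none	A
hydrogen_bond	none	C
hydrogen_bond	none	G
hydrogen_bond	none	I
hydrogen_bond	none	L
hydrogen_bond	none	M
hydrogen_bond	none	F
hydrogen_bond	none	P
hydrogen_bond	none	V
polarity	polar	R
polarity	polar	N
polarity	polar	D
polarity	polar	Q
polarity	polar	E
polarity	polar	H
polarity	polar	K
polarity	polar	S
polarity	polar	T
polarity	polar	Y
polarity	nonpolar	A
polarity	nonpolar	C
polarity	nonpolar	G
polarity	nonpolar	I
polarity	nonpolar	L
polarity	nonpolar	M
polarity	nonpolar	F
polarity	nonpolar	P
polarity	nonpolar	W
polarity	nonpolar	V
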