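# Amino-acid class memberships used for CDR positional profiles.
# One row per (scheme, class); `aa` lists the one-letter members.
# Transcribed from the standard IMGT classification of the 20 common
# amino acids (hydropathy, volume, chemical characteristics, charge,
# hydrogen donor/acceptor atoms, polarity). Editable: correcting a
# membership here changes the profiles without a code change.
scheme	class	aa
hydropathy	hydrophobic	ACFILMVW
hydropathy	neutral	GHPSTY
hydropathy	hydrophilic	DEKNQR
volume	very_small	AGS
volume	small	CDNPT
volume	medium	EHQV
volume	large	IKLMR
volume	very_large	FWY
chemical	aliphatic	AGILPV
chemical	aromatic	FWY
chemical	sulfur	CM
chemical	hydroxyl	ST
chemical	basic	HKR
chemical	acidic	DE
chemical	amide	NQ
charge	positive	HKR
charge	negative	DE
charge	uncharged	ACFGILMNPQSTVWY
hydrogen	donor	KNQRW
hydrogen	acceptor	DE
hydrogen	donor_and_acceptor	HSTY
hydrogen	none	ACFGILMPV
polarity	polar	DEHKNQRSTY
polarity	nonpolar	ACFGILMPVW
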