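# CAPN3 substrate peptide panel: 13 motif-bearing peptides plus the
# uncleaved AHNAK-repeat peptide. Labels: cleaved (+), partial (+/-),
# not_cleaved (-), nd (not determined in the cleavage assay).
sequence	label	source	note
VPSANIEGLE	cleaved	AHNAK	AHNAK-N
LPAIHVEGLD	partial	AHNAK	AHNAK-C1
LPGIGVQGLE	partial	AHNAK	AHNAK-C2
VEECYVSELD	cleaved	FLNC	Filamin C
ITKECVMRVD	cleaved	TLN1	Talin
IKKKLVQRLE	cleaved	TLN1	Talin
LYPEPVRVLE	cleaved	TTN	Titin 1607-2167
VRYDGIHYLD	cleaved	TTN	Titin 1607-2167
LTTERLVHVD	cleaved	TTN	Titin 741-948
VKYEGIGPVD	partial	SORBS3	Vinexin
VWYFGLHYVD	partial	EZR	Ezrin
IGEETVITVD	nd	FLNA	Filamin A
LEECYVTEID	nd	FLNA	Filamin A
VPDVSLEGPE	not_cleaved	AHNAK	AHNAK-R
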