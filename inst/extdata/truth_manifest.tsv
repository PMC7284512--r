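# Truth manifest for the reconstructed 73-accession Liriope/Ophiopogon collection.
# Per-accession outcomes transcribed from the published verification narrative; rows
# not individually recoverable from the text are filled to match the printed category
# totals and flagged reconstructed=yes (see package vignette, "Reconstructed collection").
# Printed totals enforced at load time: 73 tested; 36 confirmed; 4 newly identified;
# 33 misidentified (7 genus-level, 26 species-level); 46 Liriope-collection rows with
# 27 confirmed; 9 accessions with a Type 3 rbcL haplotype.
accession_id	collection	original_label	true_species	rbcl_type	its_clade	reconstructed
BTG_601	Liriope	Liriope muscari	Liriope muscari	Type 6	Liriope-muscari	yes
BTG_602	Liriope	Liriope muscari	Liriope muscari	Type 6	Liriope-muscari	yes
BTG_603	Liriope	Liriope muscari	Liriope muscari	Type 6	Liriope-muscari	yes
BTG_604	Liriope	Liriope muscari	Liriope muscari	Type 6	Liriope-muscari	yes
BTG_605	Liriope	Liriope muscari	Liriope muscari	Type 6	Liriope-muscari	yes
BTG_606	Liriope	Liriope muscari	Liriope muscari	Type 6	Liriope-muscari	yes
BTG_607	Liriope	Liriope muscari	Liriope muscari	Type 6	Liriope-muscari	yes
BTG_608	Liriope	Liriope muscari	Liriope muscari	Type 6	Liriope-muscari	yes
BTG_609	Liriope	Liriope muscari	Liriope muscari	Type 6	Liriope-muscari	yes
BTG_610	Liriope	Liriope muscari	Liriope muscari	Type 6	Liriope-muscari	yes
BTG_611	Liriope	Liriope muscari	Liriope muscari	Type 6	Liriope-muscari	yes
BTG_612	Liriope	Liriope muscari	Liriope muscari	Type 6	Liriope-muscari	yes
BTG_613	Liriope	Liriope muscari	Liriope muscari	Type 6	Liriope-muscari	yes
BTG_614	Liriope	Liriope muscari	Liriope muscari	Type 6	Liriope-muscari	yes
BTG_615	Liriope	Liriope muscari	Liriope muscari	Type 6	Liriope-muscari	yes
BTG_616	Liriope	Liriope muscari	Liriope muscari	Type 6	Liriope-muscari	yes
BTG_617	Liriope	Liriope muscari	Liriope muscari	Type 6	Liriope-muscari	yes
BTG_618	Liriope	Liriope muscari	Liriope muscari	Type 6	Liriope-muscari	yes
BTG_619	Liriope	Liriope muscari	Liriope muscari	Type 6	Liriope-muscari	yes
BTG_620	Liriope	Liriope muscari	Liriope muscari	Type 6	Liriope-muscari	yes
BTG_621	Liriope	Liriope muscari	Liriope muscari	Type 6	Liriope-muscari	yes
BTG_622	Liriope	Liriope muscari	Liriope muscari	Type 6	Liriope-muscari	yes
BTG_623	Liriope	Liriope muscari	Liriope muscari	Type 6	Liriope-muscari	yes
BTG_624	Liriope	Liriope exiliflora	Liriope spicata	Type 6	Liriope-spicata	no
BTG_625	Liriope	Liriope graminifolia	Liriope spicata	Type 6	Liriope-spicata	no
BTG_626	Liriope	Liriope graminifolia	Liriope spicata	Type 6	Liriope-spicata	no
BTG_627	Liriope	Liriope graminifolia	Liriope spicata	Type 6	Liriope-spicata	no
BTG_628	Liriope	Liriope graminifolia	Ophiopogon planiscapus	Type 3	B3a	no
BTG_630	Liriope	Liriope graminifolia	Liriope spicata	Type 6	Liriope-spicata	no
BTG_631	Liriope	Liriope muscari	Liriope muscari	Type 6	Liriope-muscari	yes
BTG_632	Liriope	Liriope muscari	Liriope muscari	Type 6	Liriope-muscari	yes
BTG_633	Liriope	Liriope muscari	Liriope muscari	Type 6	Liriope-muscari	yes
BTG_634	Liriope	Liriope muscari	Liriope muscari	Type 6	Liriope-muscari	yes
BTG_635	Liriope	Liriope muscari	Liriope spicata	Type 6	Liriope-spicata	yes
BTG_636	Liriope	Liriope muscari	Liriope spicata	Type 6	Liriope-spicata	yes
BTG_637	Liriope	Liriope muscari	Liriope spicata	Type 6	Liriope-spicata	yes
BTG_638	Liriope	Liriope muscari	Liriope spicata	Type 6	Liriope-spicata	yes
BTG_639	Liriope	Liriope muscari	Liriope spicata	Type 6	Liriope-spicata	yes
BTG_640	Liriope	Liriope minor	Liriope muscari	Type 6	Liriope-muscari	yes
BTG_641	Liriope	Liriope minor	Liriope muscari	Type 6	Liriope-muscari	yes
BTG_642	Liriope	Liriope minor	Liriope spicata	Type 6	Liriope-spicata	yes
BTG_643	Liriope	Liriope spicata	Liriope muscari	Type 6	Liriope-muscari	yes
BTG_644	Liriope	Liriope spicata	Liriope muscari	Type 6	Liriope-muscari	yes
BTG_645	Liriope	Liriope spicata	Liriope muscari	Type 6	Liriope-muscari	yes
BTG_667	Liriope	Liriope muscari	Ophiopogon jaburan	Type 5	jaburan-branch	no
BTG_677	Liriope	Liriope muscari	Ophiopogon planiscapus	Type 3	B3a	yes
BTG_678	Ophiopogon	Ophiopogon bodinieri	Ophiopogon bodinieri	Type 2	B3b	no
BTG_679	Ophiopogon	Ophiopogon chingii	Ophiopogon japonicus (II)	Type 2	B2	no
BTG_680	Ophiopogon	Ophiopogon clarkei	Ophiopogon bodinieri	Type 2	B3b	no
BTG_682	Ophiopogon	Ophiopogon intermedius	Ophiopogon japonicus (I)	Type 1	B2	no
BTG_683	Ophiopogon	Ophiopogon intermedius	Ophiopogon japonicus (I)	Type 1	B2	no
BTG_684	Ophiopogon	Ophiopogon intermedius	Ophiopogon japonicus (I)	Type 1	B2	no
BTG_685	Ophiopogon	Ophiopogon jaburan	Ophiopogon jaburan	Type 5	jaburan-branch	no
BTG_686	Ophiopogon	Ophiopogon jaburan	Ophiopogon bodinieri	Type 2	B3b	no
BTG_688	Ophiopogon	Ophiopogon japonicus	Ophiopogon japonicus (I)	Type 1	B2	no
BTG_690	Ophiopogon	Ophiopogon japonicus	Ophiopogon planiscapus	Type 3	B3a	no
BTG_691	Ophiopogon	Ophiopogon japonicus	Ophiopogon japonicus (I)	Type 1	B2	no
BTG_692	Ophiopogon	Ophiopogon japonicus	Ophiopogon japonicus (I)	Type 1	B2	no
BTG_693	Ophiopogon	Ophiopogon japonicus	Liriope muscari	Type 6	Liriope-muscari	no
BTG_695	Ophiopogon	Ophiopogon japonicus	Liriope muscari	Type 6	Liriope-muscari	no
BTG_697	Ophiopogon	Ophiopogon planiscapus	Ophiopogon planiscapus	Type 3	B3a	no
BTG_698	Ophiopogon	Ophiopogon clarkei	Ophiopogon planiscapus	Type 3	B3a	yes
BTG_699	Ophiopogon	Ophiopogon clarkei	Ophiopogon planiscapus	Type 3	B3a	yes
BTG_700	Ophiopogon	Ophiopogon planiscapus	Ophiopogon planiscapus	Type 3	B3a	no
BTG_701	Ophiopogon	Ophiopogon planiscapus	Ophiopogon planiscapus	Type 3	B3a	no
BTG_702	Ophiopogon	Ophiopogon planiscapus	Ophiopogon planiscapus	Type 3	B3a	no
BTG_703	Ophiopogon	Ophiopogon sp.	Ophiopogon bodinieri	Type 2	B3b	no
BTG_704	Ophiopogon	Ophiopogon wallichianus	Ophiopogon bodinieri	Type 2	B3b	no
BTG_705	Ophiopogon	Ophiopogon sp.	Ophiopogon japonicus (I)	Type 1	B2	no
BTG_706	Ophiopogon	Ophiopogon sp.	Ophiopogon japonicus (I)	Type 1	B2	no
BTG_708	Ophiopogon	Ophiopogon sp.	Ophiopogon japonicus (I)	Type 1	B2	no
BTG_709	Ophiopogon	Ophiopogon sp.	Liriope muscari	Type 6	Liriope-muscari	no
BTG_711	Ophiopogon	Ophiopogon sp.	Liriope muscari	Type 6	Liriope-muscari	no
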