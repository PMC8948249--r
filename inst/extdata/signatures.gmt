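arterial_ec_markers	arterial endothelial marker genes (Cdh5/Dll4/Efnb2/Hey1)	Cdh5	Dll4	Efnb2	Hey1
hsc_precursor_core	nine-gene HSC precursor co-expression signature	Gfi1	Mycn	Pdzk1ip1	Procr	Dll4	Vwf	Cdkn1c	Pbx1	Mllt3
hsc_marker_core	HSC marker genes expressed by in vitro HSC colonies	Pdzk1ip1	Procr	Fgd5	Vwf
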