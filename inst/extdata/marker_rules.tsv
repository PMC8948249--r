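type_name	required_all	required_any	forbidden
arterial_EC	Cdh5;Dll4;Efnb2;Hey1		Runx1;Gfi1;Nr2f2;Nrp2
HSC_precursor	Gfi1;Mycn;Pdzk1ip1;Procr;Dll4;Vwf;Cdkn1c;Pbx1;Mllt3		Flt3;Il7r;Fcgr3;Csf3r
progenitor	Runx1	Flt3;Il7r;Fcgr3;Csf3r	
HSC_type	Runx1;Pdzk1ip1;Vwf		Cd48;Itgal
HPC_type		Cd48;Itgal	
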