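name	peptide
V5	GKPIPNPLLGLDST
HA	YPYDVPDYA
MYC	EQKLISEEDL
FLAG	DYKDDDDK
ALFA	SRLEEELRRRLTE
OLLAS	SGFANELGPRLMGK
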