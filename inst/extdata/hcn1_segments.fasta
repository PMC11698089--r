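>hHCN1_S3 offset=220 S3 transmembrane segment region
SWFVVDFISSIPVDYIFLIVEKGMDSEVYK
>hHCN1_S6 offset=352 S6 pore helix peptide
AMSHMLCIGYGAQAPVSMSDLWITMLSMIVGATCYAMFVGHATALIQSLDSSR
>hHCN1_CNBD_A offset=469 CNBD A-helix peptide
LVATMPLFANADPNFVTAMLSK
>hHCN1_CNBD_C offset=582 CNBD C-helix peptide
AFETVAIDRLDR
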