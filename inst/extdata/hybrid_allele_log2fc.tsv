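gene	log2fc_nonhybrid	log2fc_hybrid
Rpl32	0.56469732	-0.05277919
CG30486	0.14792807	0.5723672
Obp56f	-1.35872671	-0.91834038
CG11598	-0.01453576	-0.25291426
CG15117	2.50180615	2.31701893
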