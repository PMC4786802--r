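id	smiles	alt_smiles	violates
ethanol	CCO	OCC	
glycerol	OCC(O)CO	C(CO)(O)CO	
nma	CNC(C)=O	O=C(C)NC	
morpholine	C1COCCN1	N1CCOCC1	
lactic	CC(O)C(=O)O	OC(=O)C(C)O	
dmso	CS(C)=O	O=S(C)C	
urea	NC(N)=O	O=C(N)N	
glycolamide	NC(=O)CO	OCC(N)=O	
raffinose	OCC1OC(OCC2OC(OC3(CO)OC(CO)C(O)C3O)C(O)C(O)C2O)C(O)C(O)C1O		mw<450,clogp_-3_1,sfi_-3_1,tpsa<110,hbd_0_5,hba_0_5,rotb_0_6
glucuronic	OC1OC(C(=O)O)C(O)C(O)C1O		clogp_-3_1,sfi_-3_1,tpsa<110,hba_0_5
octane	CCCCCCCC		clogp_-3_1,sfi_-3_1
teg	OCCOCCOCCO		rotb_0_6
peg4	OCCOCCOCCOCCO		rotb_0_6
succinate2	O=C([O-])CCC(=O)[O-]		charge_-1_1
sorbitol	OCC(O)C(O)C(O)C(O)CO		clogp_-3_1,sfi_-3_1,tpsa<110,hbd_0_5,hba_0_5
pyridine	c1ccncc1		clogp_-3_1,sfi_-3_1
toluene	Cc1ccccc1		clogp_-3_1,sfi_-3_1
quinone	O=C1C=CC(=O)C=C1		pains,reactive
rhodanine	O=C1CSC(=S)N1		pains
catechol	Oc1ccccc1O		clogp_-3_1,sfi_-3_1,pains
bzcl	O=C(Cl)c1ccccc1		clogp_-3_1,sfi_-3_1,reactive
ac2o	CC(=O)OC(=O)C		reactive
benzaldehyde	O=Cc1ccccc1		clogp_-3_1,sfi_-3_1,reactive
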