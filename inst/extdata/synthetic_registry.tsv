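gene	uniprot	type	sequence	catalytic_cys	helix_start	helix_end
UBB	P0CG47	UB	MQIFVKTLTGKTITLEVEPSDTIENVKAKIQDKEGIPPDQQRLIFAGKQLEDGRTLSDYNIQKESTLHLVLRLRGG	NA	NA	NA
E2SYN	SYN0001	E2	MADLSKGEALRVAKELSDLERDPPCSAGASLEAVKDLMAAKEGLSDEQIKAAYRKLAMKN	25	39	54
E3SYN	SYN0002	E3	MWTNYGQPFTHWDYSGTRYGHWNQTPGFYTHWDNSGQWGY	NA	NA	NA
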