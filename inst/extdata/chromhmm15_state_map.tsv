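1_Active_Promoter	open
2_Weak_Promoter	open
3_Poised_Promoter	open
4_Strong_Enhancer	open
5_Strong_Enhancer	open
6_Weak_Enhancer	open
7_Weak_Enhancer	open
8_Insulator	open
9_Txn_Transition	open
10_Txn_Elongation	open
11_Weak_Txn	open
12_Repressed	closed
13_Heterochrom_lo	closed
14_Repetitive_CNV	open
15_Repetitive_CNV	open
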