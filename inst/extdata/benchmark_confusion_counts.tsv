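predicted	reference	svm_rbf	dt	adaboost_dt	rf
WT	WT	20	16	20	20
WT	SCA1	0	2	2	2
WT	mod1	1	4	3	1
WT	mod2	0	0	0	1
WT	mod3	0	4	3	1
SCA1	WT	0	2	0	0
SCA1	SCA1	11	7	7	8
SCA1	mod1	0	2	0	0
SCA1	mod2	0	1	1	0
SCA1	mod3	0	2	3	0
mod1	WT	0	0	0	0
mod1	SCA1	0	0	2	0
mod1	mod1	12	7	10	11
mod1	mod2	0	0	0	0
mod1	mod3	0	0	0	0
mod2	WT	0	1	0	0
mod2	SCA1	0	0	0	0
mod2	mod1	0	0	0	1
mod2	mod2	14	12	11	12
mod2	mod3	0	3	0	0
mod3	WT	0	1	0	0
mod3	SCA1	0	2	0	1
mod3	mod1	0	0	0	0
mod3	mod2	1	2	3	2
mod3	mod3	16	7	10	15
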