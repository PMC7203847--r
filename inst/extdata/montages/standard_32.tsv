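label	x	y	z
Cz	0	0	0.09
E002	-0.0161110810010492	0.0147590699442485	0.08730751928304
E003	0.00299671403254749	-0.0341460107610404	0.0832170033954242
E004	0.0260920191259814	0.0340324185535801	0.0791264875078084
E005	-0.0489354351142274	-0.00865598944054883	0.0750359716201926
E006	0.0467256287128095	-0.0297230202417195	0.0709454557325767
E007	-0.0156419231233173	0.0581871743542414	0.0668549398449609
E008	-0.0297298503601111	-0.0572430177652091	0.0627644239573451
E009	0.0641039301621067	0.0234106524812255	0.0586739080697292
E010	-0.0661450034994722	0.0273036959027238	0.0545833921821134
E011	0.0315771508547802	-0.0674785372352056	0.0504928762944976
E012	0.0230794648390168	0.0735809707153585	0.0464023604068817
E013	-0.0687269010825013	-0.0398286439760827	0.0423118445192659
E014	0.0795803789275567	-0.0174955230667134	0.0382213286316501
E015	-0.0478951532391362	0.0681259269120893	0.0341308127440342
E016	-0.0109026613384272	-0.0841350850746454	0.0300402968564184
E017	0.0658957489234345	0.0555370069547402	0.0259497809688026
E018	-0.0872305006348349	0.00360725506534791	0.0218592650811867
E019	0.0625389693960599	-0.0622346274912501	0.0177687491935709
E020	-0.00410893772133578	0.0888595665329853	0.0136782333059551
E021	-0.0573356852080481	-0.0687073131218918	0.00958771741833924
E022	0.0890297063960016	0.0119788210760645	0.00549720153072342
E023	-0.0738682259683321	0.0513955876296098	0.00140668564310758
E024	0.0197445384333017	-0.0877664529149636	-0.00268383024450826
E025	0.0446193403157816	0.0778666983007925	-0.00677434613212409
E026	-0.0851152744779613	-0.0271540940528924	-0.0108648620197399
E027	0.0805653081397278	-0.0372232158202227	-0.0149553779073558
E028	-0.0339585743095568	0.0811422772690844	-0.0190458937949716
E029	-0.0294369958138349	-0.0818423473786996	-0.0231364096825874
E030	0.0759340581283609	0.0399088128131283	-0.0272269255702032
E031	-0.0815885367632953	0.0215064764515364	-0.0313174414578191
E032	0.0447501203152108	-0.0695967189485109	-0.0354079573454349
nasion	0	0.09	-0.0225
lpa	-0.09	0	-0.0225
rpa	0.09	0	-0.0225
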