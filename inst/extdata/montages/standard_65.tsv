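label	x	y	z
Cz	0	0	0.09
E002	-0.012603149059891	0.0115455169321417	0.088362105410316
E003	0.00220888666304214	-0.0251691242297276	0.0863807617772521
E004	0.0190154249367139	0.0248022545628151	0.0843994181441882
E005	-0.0356033642039831	-0.00629773381759697	0.0824180745111242
E006	0.0340644434423681	-0.0216690105591419	0.0804367308780603
E007	-0.0114483797547348	0.0425874020483644	0.0784553872449964
E008	-0.0218710978180105	-0.0421114679615335	0.0764740436119325
E009	0.0474411904171568	0.0173254466511356	0.0744926999788686
E010	-0.0492781368771674	0.0203412985526218	0.0725113563458047
E011	0.0236956724484622	-0.0506362756722473	0.0705300127127407
E012	0.0174538695061143	0.0556456863257925	0.0685486690796768
E013	-0.0524063163810256	-0.0303705315438595	0.0665673254466129
E014	0.0612170133844527	-0.0134583886653514	0.064585981813549
E015	-0.0371867289220608	0.0528942952535311	0.0626046381804851
E016	-0.00854844005159652	-0.0659677218865475	0.0606232945474211
E017	0.0522044276280686	0.0439979468723696	0.0586419509143572
E018	-0.0698657876299994	0.00288916966529701	0.0566606072812933
E019	0.0506710321196685	-0.0504244447744836	0.0546792636482294
E020	-0.00337005433629186	0.0728805321045728	0.0526979200151655
E021	-0.0476363215427523	-0.0570842338124457	0.0507165763821016
E022	0.0749872032404683	0.0100894221375574	0.0487352327490376
E023	-0.0631264817287443	0.0439217617711511	0.0467538891159737
E024	0.0171356052650447	-0.0761694834115431	0.0447725454829098
E025	0.0393650255090867	0.0686972183637351	0.0427912018498459
E026	-0.0764208998711762	-0.0243803514167825	0.040809858216782
E027	0.0737065270457092	-0.0340542849885609	0.038828514583718
E028	-0.0317000253086433	0.0757455898938324	0.0368471709506541
E029	-0.0280821059780951	-0.0780754084798473	0.0348658273175902
E030	0.0741586475925454	0.0389757067934218	0.0328844836845263
E031	-0.0817361158218911	0.0215453778177619	0.0309031400514624
E032	0.046093623075057	-0.0716861744253889	0.0289217964183984
E033	0.0145448793858839	0.0846324907312272	0.0269404527853345
E034	-0.0683651035116758	-0.0529457787945639	0.0249591091522706
E035	0.0867202621395105	-0.00718459645345063	0.0229777655192067
E036	-0.0594306961037685	0.0642428410688742	0.0209964218861428
E037	0.000429133887471921	-0.0879672816627632	0.0190150782530789
E038	0.0593767540211529	0.0654542051117146	0.0170337346200149
E039	-0.0883536777506933	-0.00818859899510258	0.015052390986951
E040	0.0709302424277839	-0.0538335251512313	0.0130710473538871
E041	-0.0159857676736103	0.0878719164652149	0.0110897037208232
E042	-0.0476883930762077	-0.0757816266803559	0.00910836008775927
E043	0.0865267611465114	0.0237133979418611	0.00712701645469534
E044	-0.0799407874358272	0.0410242922590094	0.00514567282163142
E045	0.0312661705952635	-0.084335126709422	0.00316432918856751
E046	0.0339309073725858	0.0833504293333182	0.00118298555550359
E047	-0.0813258272533212	-0.0385418272263128	-0.000798358077560325
E048	0.0859641173355872	-0.0265036561461498	-0.00277970171062426
E049	-0.0454422939006778	0.0775392182851992	-0.00476104534368817
E050	-0.0188426150860067	-0.0877467722916733	-0.00674238897675208
E051	0.0730267373057582	0.0518747735207414	-0.00872373260981599
E052	-0.0886750688370469	0.0110514030502521	-0.0107050762428799
E053	0.0577527912911906	-0.0678503489217811	-0.0126864198759438
E054	0.003236038527134	0.0887377302408323	-0.0146677635090077
E055	-0.0620819031538031	-0.0629971787636052	-0.0166491071420717
E056	0.0879357173079825	0.00449621234438889	-0.0186304507751356
E057	-0.0675369827306981	0.055802418360744	-0.0206117944081995
E058	0.0120379783516026	-0.0862823109950977	-0.0225931380412634
E059	0.0491013034150141	0.0713102857474633	-0.0245744816743273
E060	-0.0838030911451083	-0.0192828954456531	-0.0265558253073913
E061	0.0742649251784397	-0.0420755377518181	-0.0285371689404552
E062	-0.0261266643849142	0.0805358168668948	-0.0305185125735191
E063	-0.0348288331911942	-0.0763590971992951	-0.032499856206583
E064	0.0765302178363373	0.0324680245093705	-0.034481199839647
E065	-0.0775618307285141	0.02747080882577	-0.0364625434727109
nasion	0	0.09	-0.0225
lpa	-0.09	0	-0.0225
rpa	0.09	0	-0.0225
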