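study_id,n_itt_active,drop_active,n_itt_passive,drop_passive,diff,method,used_mi,used_ml
Bakker et al,234,146,78,25,not_tested,anova,yes,no
Bidargaddi et al,192,106,195,88,higher_in_active,t_test,yes,no
Bostock et al,128,5,110,4,not_tested,anova,no,no
Carissoli et al,20,0,18,0,not_tested,anova,not_reported,not_reported
Champion et al,38,9,36,3,tested_no_difference,mlm,yes,yes
Enock et al,206,38,36,0,not_tested,mlm,no,yes
Faurholt-Jepsen et al,39,6,39,5,not_tested,mlm,no,unclear
Hall et al,76,34,25,13,not_tested,mlm,no,unclear
Horsch et al,74,29,77,15,not_tested,mlm,yes,unclear
Ivanova et al,101,20,51,4,not_tested,mlm,no,yes
Kahn et al,80,1,80,0,not_tested,t_test,no,no
Krafft et al,67,15,31,5,not_tested,mlm,no,yes
Kristjansdottir et al,70,23,70,33,not_tested,t_test,no,no
Kuhn et al,62,11,58,6,tested_no_difference,anova,yes,no
Lee and Jung,102,25,104,18,not_tested,anova,no,no
Levin et al (2017),12,0,11,0,not_tested,mlm,no,unclear
Levin et al (2020),59,13,28,5,tested_no_difference,mlm,no,unclear
Ludtke et al,45,10,45,6,tested_no_difference,anova,yes,no
Lukas and Berking,16,2,15,2,not_tested,anova,no,no
Ly et al (2014),36,3,37,2,not_tested,mlm,no,yes
Ly et al (2015),14,0,14,0,not_tested,mlm,no,yes
Marx,46,2,50,0,not_tested,anova,no,no
Miner et al,25,2,24,3,not_tested,anova,yes,no
Moell et al,29,3,28,1,not_tested,anova,no,no
Oh et al,39,1,20,4,not_tested,anova,no,no
Pham et al,31,14,32,7,not_tested,anova,no,no
Proudfoot et al,242,116,230,32,higher_in_active,mlm,yes,yes
Roepke et al,190,152,93,57,higher_in_active,mlm,no,yes
Rosen et al,57,17,55,7,higher_in_active,mlm,no,yes
Schlosser et al,22,3,21,0,not_tested,anova,no,no
Stjernsward and Hansson,196,60,202,42,not_tested,anova,yes,no
Stolz et al,60,18,30,7,tested_no_difference,mlm,yes,yes
Tighe et al,31,2,30,0,not_tested,anova,no,no
van Emmerik et al,191,111,186,45,higher_in_active,mlm,yes,unclear
Versluis et al,46,9,42,3,higher_in_active,mlm,no,unclear
Yang et al,45,3,43,4,not_tested,anova,no,no
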