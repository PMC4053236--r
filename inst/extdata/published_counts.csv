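table,item,group,count,denominator
molecular,esr1_mrna_negative,MA,58,58
molecular,esr1_mrna_negative,BL,13,13
molecular,erbb2_mrna_positive,MA,38,56
molecular,erbb2_mrna_positive,BL,0,13
molecular,ar_mrna_positive,MA,58,58
molecular,ar_mrna_positive,BL,2,13
molecular,foxa1_mrna_positive,MA,58,58
molecular,foxa1_mrna_positive,BL,0,13
molecular,pik3ca_mutated,MA,11,58
molecular,pik3ca_mutated,BL,0,13
molecular,tp53_nonfunctional,MA,29,58
molecular,tp53_nonfunctional,BL,13,13
ihc,er_negative,MA,54,58
ihc,er_negative,BL,13,13
ihc,pr_negative,MA,56,58
ihc,pr_negative,BL,13,13
ihc,her2_3plus,MA,39,58
ihc,her2_3plus,BL,0,13
ihc,gcdfp15_positive,MA,33,58
ihc,gcdfp15_positive,BL,0,13
ihc,ar_positive,MA,33,57
ihc,ar_positive,BL,0,13
ihc,foxa1_positive,MA,52,58
ihc,foxa1_positive,BL,4,13
ihc,egfr_negative,MA,40,57
ihc,egfr_negative,BL,4,13
ihc,ck56_negative,MA,51,57
ihc,ck56_negative,BL,5,13
ihc,ck17_negative,MA,54,57
ihc,ck17_negative,BL,5,13
signature,combined_rule_positive_er_negative,MA,51,54
signature,combined_rule_positive_er_negative,BL,0,13
signature,ar_positive_er_negative,MA,31,53
signature,ar_positive_er_negative,BL,0,13
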