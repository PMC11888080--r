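method,subgroup,category,subcategory,n
rule,LR,confirmed_error,same_body_part,421
rule,LR,confirmed_error,not_same_body_part,182
rule,LR,confirmed_nonerror,unspecified_side,39
rule,LR,confirmed_nonerror,no_laterality,131
rule,LR,confirmed_nonerror,general_diagnosis,251
rule,LR,confirmed_nonerror,proximity,4
rule,LR,confirmed_nonerror,combination,78
rule,RL,confirmed_error,same_body_part,390
rule,RL,confirmed_error,not_same_body_part,151
rule,RL,confirmed_nonerror,unspecified_side,50
rule,RL,confirmed_nonerror,no_laterality,271
rule,RL,confirmed_nonerror,general_diagnosis,129
rule,RL,confirmed_nonerror,proximity,4
rule,RL,confirmed_nonerror,combination,69
aop,LR,confirmed_error,same_body_part,404
aop,LR,confirmed_error,not_same_body_part,172
aop,LR,confirmed_nonerror,unspecified_side,17
aop,LR,confirmed_nonerror,no_laterality,34
aop,LR,confirmed_nonerror,general_diagnosis,58
aop,LR,confirmed_nonerror,proximity,2
aop,LR,confirmed_nonerror,combination,10
aop,RL,confirmed_error,same_body_part,376
aop,RL,confirmed_error,not_same_body_part,148
aop,RL,confirmed_nonerror,unspecified_side,17
aop,RL,confirmed_nonerror,no_laterality,75
aop,RL,confirmed_nonerror,general_diagnosis,25
aop,RL,confirmed_nonerror,proximity,4
aop,RL,confirmed_nonerror,combination,10
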