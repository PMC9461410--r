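dose,stratum_type,stratum,tier,count
2,all,all,none,181
2,all,all,mild,102
2,all,all,severe,52
3,all,all,none,655
3,all,all,mild,404
3,all,all,severe,120
2,sex,female,none,96
2,sex,female,mild,61
2,sex,female,severe,37
2,sex,male,none,85
2,sex,male,mild,41
2,sex,male,severe,15
3,sex,female,none,355
3,sex,female,mild,235
3,sex,female,severe,77
3,sex,male,none,300
3,sex,male,mild,169
3,sex,male,severe,43
2,age_group,18-55,none,69
2,age_group,18-55,mild,79
2,age_group,18-55,severe,37
2,age_group,>55,none,112
2,age_group,>55,mild,23
2,age_group,>55,severe,15
3,age_group,18-55,none,326
3,age_group,18-55,mild,256
3,age_group,18-55,severe,87
3,age_group,>55,none,329
3,age_group,>55,mild,148
3,age_group,>55,severe,33
2,underlying_condition,yes,none,61
2,underlying_condition,yes,mild,14
2,underlying_condition,yes,severe,8
2,underlying_condition,no,none,117
2,underlying_condition,no,mild,83
2,underlying_condition,no,severe,43
3,underlying_condition,yes,none,278
3,underlying_condition,yes,mild,141
3,underlying_condition,yes,severe,38
3,underlying_condition,no,none,374
3,underlying_condition,no,mild,261
3,underlying_condition,no,severe,82
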