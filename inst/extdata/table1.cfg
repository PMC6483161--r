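# Modelled scenarios: prevalence, relative risk, response and the NNT.
# Sixteen columns: rare (2%) and common (20%) prevalence over a realistic
# range of score strengths, then lower and differential effectiveness.
name = table1

[column] rare_reasonable_1
prevalence = 0.02
target = 0.05
rr = 4.7
effect_target = 0.90

[column] rare_reasonable_2
prevalence = 0.02
target = 0.10
rr = 3.0
effect_target = 0.90

[column] rare_reasonable_3
prevalence = 0.02
target = 0.15
rr = 2.4
effect_target = 0.90

[column] rare_reasonable_4
prevalence = 0.02
target = 0.20
rr = 2.0
effect_target = 0.90

[column] rare_exceptional_1
prevalence = 0.02
target = 0.05
rr = 10
effect_target = 0.90

[column] rare_exceptional_2
prevalence = 0.02
target = 0.10
rr = 9.0
effect_target = 0.90

[column] rare_exceptional_3
prevalence = 0.02
target = 0.15
rr = 5.6
effect_target = 0.90

[column] rare_exceptional_4
prevalence = 0.02
target = 0.20
rr = 4.0
effect_target = 0.90

[column] common_predictive_1
prevalence = 0.20
target = 0.05
rr = 4.7
effect_target = 0.90

[column] common_predictive_2
prevalence = 0.20
target = 0.10
rr = 3.0
effect_target = 0.90

[column] common_predictive_3
prevalence = 0.20
target = 0.15
rr = 2.4
effect_target = 0.90

[column] common_predictive_4
prevalence = 0.20
target = 0.20
rr = 2.0
effect_target = 0.90

[column] less_effective_1
prevalence = 0.20
target = 0.05
rr = 4.7
effect_target = 0.50

[column] less_effective_2
prevalence = 0.20
target = 0.10
rr = 4.0
effect_target = 0.50

[column] differential_1
prevalence = 0.20
target = 0.05
rr = 4.7
effect_target = 0.75
effect_remainder = 0.25

[column] differential_2
prevalence = 0.20
target = 0.10
rr = 3.0
effect_target = 0.75
effect_remainder = 0.25
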