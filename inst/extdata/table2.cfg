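# Approximate observed scenarios: opioid use disorder, coronary events
# (annual prevalence), and osteoporotic bone fracture.
name = table2

[column] opioid_1
prevalence = 0.05
target = 0.01
rr = 6
effect_target = 0.80

[column] opioid_2
prevalence = 0.08
target = 0.05
rr = 8.7
effect_target = 0.80

[column] opioid_3
prevalence = 0.08
target = 0.33
rr = 2
effect_target = 0.50

[column] cad_1
prevalence = 0.022
target = 0.05
rr = 3.3
effect_target = 0.25

[column] cad_2
prevalence = 0.12
target = 0.20
rr = 2.2
effect_target = 0.25

[column] cad_3
prevalence = 0.12
target = 0.50
rr = 1.6
effect_target = 0.25

[column] cad_4
prevalence = 0.12
target = 0.80
rr = 1.2
effect_target = 0.25

[column] fracture_1
prevalence = 0.16
target = 0.08
rr = 3
effect_target = 0.60

[column] fracture_2
prevalence = 0.16
target = 0.10
rr = 5
effect_target = 0.60

[column] fracture_3
prevalence = 0.16
target = 0.50
rr = 2.3
effect_target = 0.60

[column] fracture_4
prevalence = 0.16
target = 0.80
rr = 1.3
effect_target = 0.60
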