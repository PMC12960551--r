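# Reliability study design: 12 participants, both feet, two
# weight-bearing conditions, three guided raters, one attempt each.
n_subjects = 12
feet_per_subject = 2
conditions = NWB,HWB
raters = 3
rater_mode = guided
repetitions = 1
seed = 1
resolution = 64
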