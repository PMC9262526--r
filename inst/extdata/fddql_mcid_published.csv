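domain,distribution_based,anchor_based,weighted_published
activities,3.2835,3.1250,3.2043
anxiety,3.8954,10.0000,6.9477
diet,3.8171,3.4301,3.6236
sleep,3.9179,4.1667,4.0423
discomfort,2.8898,5.5556,4.2227
health_perceptions,3.3792,4.1667,3.7730
coping,4.2505,8.3333,6.2919
stress,4.2640,2.7778,3.5209
total,2.3709,6.7262,4.5485
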