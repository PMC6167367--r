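onset	duration	trial_type	run
4	4	faces	1
24	4	shapes	1
44	4	faces	1
64	4	shapes	1
4	4	shapes	2
24	4	faces	2
44	4	shapes	2
64	4	faces	2
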