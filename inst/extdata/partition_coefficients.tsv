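chemical	tissue	pc
DEHTP	adipose	47.2
DEHTP	kidney	3.7
DEHTP	liver	5.9
DEHTP	muscle	3.3
DEHTP	blood_cells	3.0
DEHTP	gut	7.4
DEHTP	spleen	3.7
MEHTP	adipose	20.3
MEHTP	kidney	12.2
MEHTP	liver	5.9
MEHTP	muscle	3.3
MEHTP	blood_cells	3.0
MEHTP	gut	7.4
MEHTP	spleen	3.7
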