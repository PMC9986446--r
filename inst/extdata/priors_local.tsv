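name	family	p1	p2	lower	upper
FracMetabMOH	uniform	0.045	0.085	NA	NA
FracMetab2cx	uniform	0.0047368	0.0152632	NA	NA
FracMetab5cx	uniform	0.3002632	0.5497368	NA	NA
K1_DEHTP_Liver	halfnormal	3.0542	NA	NA	NA
FracDOSEHep	uniform	0.0050526	0.7029474	NA	NA
BELLYPERM	uniform	0.0042105	7.4357895	NA	NA
GIPERM1	uniform	0.0010526	9.9589474	NA	NA
GIPERM2	uniform	0.1805263	30.1594737	NA	NA
Gutlag	uniform	0	3.9747368	NA	NA
FracDoseLymph	uniform	0.002	0.302	NA	NA
Lymphlag	uniform	0.9947368	5.0052632	NA	NA
K1_Lymph	uniform	0.0510526	3.0089474	NA	NA
MPY	normal	34	10	0	NA
MPYgu	normal	3.92	1.839	0	NA
VBldC	normal	0.05	0.01	0.0335515	0.0664485
VliC	normal	0.0309	0.008	0.0177412	0.0440588
VguC	normal	0.015	0.0017	0.0122038	0.0177962
VkiC	normal	0.0058	0.0015	0.0033327	0.0082673
QguC	normal	0.15	0.0308673	0.0992266	0.2007734
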