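name	family	p1	p2	lower	upper
FB_DEHTP	uniform	0.8	1.0	NA	NA
FB_MEHTP	uniform	0.8	1.0	NA	NA
DEHTP_GUT_half_life	normal	30	10	0	NA
DEHTP_half_life	halfnormal	10	NA	NA	NA
Pbab	uniform	1	30	NA	NA
Pgub	uniform	1	50	NA	NA
Plib	uniform	1	50	NA	NA
PbaM	uniform	1	50	NA	NA
PliM	uniform	1	30	NA	NA
PguM	uniform	1	30	NA	NA
K1_2cx	uniform	0	5	NA	NA
K1_MOH	uniform	0	5	NA	NA
K1_5cx	uniform	0	5	NA	NA
escapeFracgu	uniform	0	1	NA	NA
escapeFracli	uniform	0	1	NA	NA
sigma_OH	halfnormal	1	NA	NA	NA
sigma_2cx	halfnormal	1	NA	NA	NA
sigma_5cx	halfnormal	1	NA	NA	NA
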