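# genes: lexA recA recF rpoS rpoD umuDC dinI ssB rpoH
recA	lexA	+
recF	lexA	+
rpoD	lexA	+
dinI	lexA	+
ssB	lexA	-
umuDC	lexA	-
recF	recA	+
rpoD	recA	+
dinI	recA	+
lexA	recA	-
ssB	recA	-
umuDC	recA	-
rpoD	recF	+
rpoS	recF	+
ssB	recF	-
umuDC	recF	-
rpoD	rpoS	+
recF	rpoD	+
recA	rpoD	+
dinI	rpoD	+
rpoH	rpoD	+
umuDC	rpoD	-
ssB	rpoD	-
lexA	rpoD	-
rpoD	umuDC	+
recF	umuDC	+
recA	umuDC	+
dinI	umuDC	-
ssB	umuDC	-
lexA	umuDC	-
rpoD	dinI	+
recF	dinI	+
recA	dinI	+
umuDC	dinI	-
ssB	dinI	-
lexA	dinI	-
dinI	ssB	+
rpoD	ssB	+
recF	ssB	+
recA	ssB	+
umuDC	ssB	-
lexA	ssB	-
rpoD	rpoH	+
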