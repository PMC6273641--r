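gene	product
thaRI	LuxR transcriptional regulator
thaRII	LuxR transcriptional regulator
thaRIII	LuxR transcriptional regulator
thaRIV	LuxR transcriptional regulator
thaOI	P450 monooxygenase
thaF	ferredoxin
thaBI	polyketide synthase type I
thaBII	polyketide synthase type I
thaBIII	polyketide synthase type I
thaBIV	polyketide synthase type I
thaC	crotonyl-CoA carboxylase/reductase
thaOII	P450 monooxygenase
thaT	MFS transporter
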