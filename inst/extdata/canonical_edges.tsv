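from	to
PI3K	PDK1
PI3K	AKT
PDK1	AKT
AKT	mTOR
AKT	GSK3B
mTOR	p70S6K
p70S6K	S6RIB
AMPK	mTOR
RAF	MEK
MEK	ERK
ERK	p70S6K
PTEN	PI3K
p53	CHK1
FAK	PI3K
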