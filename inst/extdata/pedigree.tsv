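id	sex	father_id	mother_id
FATHER	male	0	0
MOTHER	female	0	0
DAUGHTER	female	FATHER	MOTHER
SON	male	FATHER	MOTHER
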