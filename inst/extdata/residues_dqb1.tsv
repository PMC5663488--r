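# Curated two-field consensus residues of the mature DQbeta chain at the scanned
# polymorphic positions (23, 56, 57, 70, 71). Implementer-curated from public
# protein alignments; verify against the current IMGT/HLA release before biological use.
allele	position	residue
DQB1*03:01	23	V
DQB1*03:01	56	P
DQB1*03:01	57	D
DQB1*03:01	70	G
DQB1*03:01	71	T
DQB1*03:02	23	V
DQB1*03:02	56	P
DQB1*03:02	57	A
DQB1*03:02	70	G
DQB1*03:02	71	T
DQB1*03:03	23	V
DQB1*03:03	56	P
DQB1*03:03	57	D
DQB1*03:03	70	G
DQB1*03:03	71	T
DQB1*04:01	23	L
DQB1*04:01	56	L
DQB1*04:01	57	D
DQB1*04:01	70	E
DQB1*04:01	71	D
DQB1*04:02	23	L
DQB1*04:02	56	L
DQB1*04:02	57	D
DQB1*04:02	70	E
DQB1*04:02	71	D
DQB1*05:01	23	V
DQB1*05:01	56	P
DQB1*05:01	57	V
DQB1*05:01	70	G
DQB1*05:01	71	T
DQB1*05:02	23	V
DQB1*05:02	56	P
DQB1*05:02	57	S
DQB1*05:02	70	G
DQB1*05:02	71	T
DQB1*05:03	23	V
DQB1*05:03	56	P
DQB1*05:03	57	D
DQB1*05:03	70	G
DQB1*05:03	71	T
DQB1*06:01	23	V
DQB1*06:01	56	P
DQB1*06:01	57	D
DQB1*06:01	70	G
DQB1*06:01	71	T
DQB1*06:02	23	V
DQB1*06:02	56	P
DQB1*06:02	57	D
DQB1*06:02	70	G
DQB1*06:02	71	T
DQB1*06:03	23	V
DQB1*06:03	56	P
DQB1*06:03	57	D
DQB1*06:03	70	G
DQB1*06:03	71	T
DQB1*06:04	23	V
DQB1*06:04	56	P
DQB1*06:04	57	V
DQB1*06:04	70	G
DQB1*06:04	71	T
DQB1*99:01	23	X
DQB1*99:01	56	X
DQB1*99:01	57	X
DQB1*99:01	70	X
DQB1*99:01	71	X
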