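# Curated two-field consensus residues of the mature DRbeta chain at the scanned
# polymorphic positions (11, 13, 33, 57, 70-74, 96). Implementer-curated from public
# protein alignments; verify against the current IMGT/HLA release before biological use.
allele	position	residue
DRB1*01:01	11	L
DRB1*01:01	13	F
DRB1*01:01	33	H
DRB1*01:01	57	D
DRB1*01:01	70	Q
DRB1*01:01	71	R
DRB1*01:01	72	R
DRB1*01:01	73	A
DRB1*01:01	74	A
DRB1*01:01	96	E
DRB1*03:01	11	S
DRB1*03:01	13	S
DRB1*03:01	33	N
DRB1*03:01	57	D
DRB1*03:01	70	Q
DRB1*03:01	71	K
DRB1*03:01	72	R
DRB1*03:01	73	G
DRB1*03:01	74	R
DRB1*03:01	96	E
DRB1*04:01	11	V
DRB1*04:01	13	H
DRB1*04:01	33	H
DRB1*04:01	57	D
DRB1*04:01	70	Q
DRB1*04:01	71	K
DRB1*04:01	72	R
DRB1*04:01	73	A
DRB1*04:01	74	A
DRB1*04:01	96	E
DRB1*04:03	11	V
DRB1*04:03	13	H
DRB1*04:03	33	H
DRB1*04:03	57	D
DRB1*04:03	70	Q
DRB1*04:03	71	R
DRB1*04:03	72	R
DRB1*04:03	73	A
DRB1*04:03	74	E
DRB1*04:03	96	E
DRB1*04:04	11	V
DRB1*04:04	13	H
DRB1*04:04	33	H
DRB1*04:04	57	D
DRB1*04:04	70	Q
DRB1*04:04	71	R
DRB1*04:04	72	R
DRB1*04:04	73	A
DRB1*04:04	74	A
DRB1*04:04	96	E
DRB1*04:05	11	V
DRB1*04:05	13	H
DRB1*04:05	33	H
DRB1*04:05	57	S
DRB1*04:05	70	Q
DRB1*04:05	71	R
DRB1*04:05	72	R
DRB1*04:05	73	A
DRB1*04:05	74	A
DRB1*04:05	96	Y
DRB1*04:06	11	V
DRB1*04:06	13	H
DRB1*04:06	33	H
DRB1*04:06	57	D
DRB1*04:06	70	Q
DRB1*04:06	71	R
DRB1*04:06	72	R
DRB1*04:06	73	A
DRB1*04:06	74	E
DRB1*04:06	96	E
DRB1*04:07	11	V
DRB1*04:07	13	H
DRB1*04:07	33	H
DRB1*04:07	57	D
DRB1*04:07	70	Q
DRB1*04:07	71	R
DRB1*04:07	72	R
DRB1*04:07	73	A
DRB1*04:07	74	E
DRB1*04:07	96	E
DRB1*04:10	11	V
DRB1*04:10	13	H
DRB1*04:10	33	H
DRB1*04:10	57	D
DRB1*04:10	70	Q
DRB1*04:10	71	R
DRB1*04:10	72	R
DRB1*04:10	73	A
DRB1*04:10	74	A
DRB1*04:10	96	E
DRB1*07:01	11	G
DRB1*07:01	13	Y
DRB1*07:01	33	H
DRB1*07:01	57	D
DRB1*07:01	70	D
DRB1*07:01	71	R
DRB1*07:01	72	R
DRB1*07:01	73	G
DRB1*07:01	74	Q
DRB1*07:01	96	E
DRB1*08:02	11	S
DRB1*08:02	13	G
DRB1*08:02	33	H
DRB1*08:02	57	D
DRB1*08:02	70	D
DRB1*08:02	71	E
DRB1*08:02	72	R
DRB1*08:02	73	A
DRB1*08:02	74	L
DRB1*08:02	96	E
DRB1*08:03	11	S
DRB1*08:03	13	G
DRB1*08:03	33	H
DRB1*08:03	57	D
DRB1*08:03	70	D
DRB1*08:03	71	E
DRB1*08:03	72	R
DRB1*08:03	73	A
DRB1*08:03	74	L
DRB1*08:03	96	E
DRB1*08:09	11	S
DRB1*08:09	13	G
DRB1*08:09	33	H
DRB1*08:09	57	D
DRB1*08:09	70	D
DRB1*08:09	71	E
DRB1*08:09	72	R
DRB1*08:09	73	A
DRB1*08:09	74	L
DRB1*08:09	96	E
DRB1*09:01	11	D
DRB1*09:01	13	F
DRB1*09:01	33	H
DRB1*09:01	57	D
DRB1*09:01	70	R
DRB1*09:01	71	R
DRB1*09:01	72	R
DRB1*09:01	73	A
DRB1*09:01	74	E
DRB1*09:01	96	E
DRB1*10:01	11	V
DRB1*10:01	13	F
DRB1*10:01	33	H
DRB1*10:01	57	D
DRB1*10:01	70	R
DRB1*10:01	71	R
DRB1*10:01	72	R
DRB1*10:01	73	A
DRB1*10:01	74	A
DRB1*10:01	96	E
DRB1*11:01	11	S
DRB1*11:01	13	S
DRB1*11:01	33	H
DRB1*11:01	57	D
DRB1*11:01	70	D
DRB1*11:01	71	R
DRB1*11:01	72	R
DRB1*11:01	73	A
DRB1*11:01	74	A
DRB1*11:01	96	E
DRB1*12:01	11	S
DRB1*12:01	13	S
DRB1*12:01	33	H
DRB1*12:01	57	D
DRB1*12:01	70	D
DRB1*12:01	71	R
DRB1*12:01	72	R
DRB1*12:01	73	A
DRB1*12:01	74	A
DRB1*12:01	96	E
DRB1*12:02	11	S
DRB1*12:02	13	S
DRB1*12:02	33	H
DRB1*12:02	57	D
DRB1*12:02	70	D
DRB1*12:02	71	R
DRB1*12:02	72	R
DRB1*12:02	73	A
DRB1*12:02	74	A
DRB1*12:02	96	E
DRB1*13:01	11	S
DRB1*13:01	13	S
DRB1*13:01	33	N
DRB1*13:01	57	D
DRB1*13:01	70	D
DRB1*13:01	71	E
DRB1*13:01	72	R
DRB1*13:01	73	A
DRB1*13:01	74	A
DRB1*13:01	96	E
DRB1*13:02	11	S
DRB1*13:02	13	S
DRB1*13:02	33	N
DRB1*13:02	57	D
DRB1*13:02	70	D
DRB1*13:02	71	E
DRB1*13:02	72	R
DRB1*13:02	73	A
DRB1*13:02	74	A
DRB1*13:02	96	E
DRB1*14:02	11	S
DRB1*14:02	13	S
DRB1*14:02	33	N
DRB1*14:02	57	D
DRB1*14:02	70	Q
DRB1*14:02	71	R
DRB1*14:02	72	R
DRB1*14:02	73	A
DRB1*14:02	74	A
DRB1*14:02	96	E
DRB1*14:03	11	S
DRB1*14:03	13	S
DRB1*14:03	33	N
DRB1*14:03	57	D
DRB1*14:03	70	Q
DRB1*14:03	71	R
DRB1*14:03	72	R
DRB1*14:03	73	A
DRB1*14:03	74	E
DRB1*14:03	96	E
DRB1*14:04	11	S
DRB1*14:04	13	S
DRB1*14:04	33	N
DRB1*14:04	57	D
DRB1*14:04	70	Q
DRB1*14:04	71	R
DRB1*14:04	72	R
DRB1*14:04	73	A
DRB1*14:04	74	E
DRB1*14:04	96	E
DRB1*14:05	11	S
DRB1*14:05	13	S
DRB1*14:05	33	N
DRB1*14:05	57	D
DRB1*14:05	70	Q
DRB1*14:05	71	R
DRB1*14:05	72	R
DRB1*14:05	73	A
DRB1*14:05	74	E
DRB1*14:05	96	E
DRB1*14:06	11	S
DRB1*14:06	13	S
DRB1*14:06	33	N
DRB1*14:06	57	D
DRB1*14:06	70	Q
DRB1*14:06	71	R
DRB1*14:06	72	R
DRB1*14:06	73	A
DRB1*14:06	74	A
DRB1*14:06	96	E
DRB1*14:07	11	S
DRB1*14:07	13	S
DRB1*14:07	33	N
DRB1*14:07	57	D
DRB1*14:07	70	Q
DRB1*14:07	71	R
DRB1*14:07	72	R
DRB1*14:07	73	A
DRB1*14:07	74	E
DRB1*14:07	96	E
DRB1*14:29	11	S
DRB1*14:29	13	S
DRB1*14:29	33	N
DRB1*14:29	57	D
DRB1*14:29	70	Q
DRB1*14:29	71	R
DRB1*14:29	72	R
DRB1*14:29	73	A
DRB1*14:29	74	E
DRB1*14:29	96	E
DRB1*14:54	11	S
DRB1*14:54	13	S
DRB1*14:54	33	N
DRB1*14:54	57	D
DRB1*14:54	70	Q
DRB1*14:54	71	R
DRB1*14:54	72	R
DRB1*14:54	73	A
DRB1*14:54	74	E
DRB1*14:54	96	E
DRB1*15:01	11	P
DRB1*15:01	13	R
DRB1*15:01	33	H
DRB1*15:01	57	D
DRB1*15:01	70	Q
DRB1*15:01	71	A
DRB1*15:01	72	R
DRB1*15:01	73	A
DRB1*15:01	74	A
DRB1*15:01	96	E
DRB1*15:02	11	P
DRB1*15:02	13	R
DRB1*15:02	33	H
DRB1*15:02	57	D
DRB1*15:02	70	Q
DRB1*15:02	71	A
DRB1*15:02	72	R
DRB1*15:02	73	A
DRB1*15:02	74	A
DRB1*15:02	96	E
DRB1*16:02	11	P
DRB1*16:02	13	R
DRB1*16:02	33	H
DRB1*16:02	57	D
DRB1*16:02	70	Q
DRB1*16:02	71	R
DRB1*16:02	72	R
DRB1*16:02	73	A
DRB1*16:02	74	E
DRB1*16:02	96	E
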