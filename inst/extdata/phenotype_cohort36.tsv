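participant_id	group	subtype	ivp_score	sex	age	race
IBS01	IBS	D	81	male	44	Caucasian
IBS02	IBS	M	77	male	15	Caucasian
IBS03	IBS	D	65	female	30	African-American
IBS04	IBS	C	64	male	45	African-American
IBS05	IBS	D	54	male	26	African-American
IBS06	IBS	C	48	female	32	African-American
IBS07	IBS	C	42	female	26	African-American
IBS08	IBS	D	29	female	23	African-American
IBS09	IBS	D	28	female	27	Caucasian
IBS10	IBS	C	27	female	29	African-American
IBS11	IBS	D	25	female	24	Caucasian
IBS12	IBS	C	16	male	30	Caucasian
IBS13	IBS	D	11	female	26	Asian
IBS14	IBS	D	11	female	24	Caucasian
IBS15	IBS	C	5	female	24	Caucasian
IBS16	IBS	C	4	male	26	Caucasian
IBS17	IBS	M	0	male	31	Asian
IBS18	IBS	C	0	female	24	Mixed/Other
HC01	HC	NONE	10	female	30	Caucasian
HC02	HC	NONE	6.2	female	23	Mixed/Other
HC03	HC	NONE	0	female	24	African-American
HC04	HC	NONE	0	male	23	Caucasian
HC05	HC	NONE	0	male	40	Caucasian
HC06	HC	NONE	0	male	29	Asian
HC07	HC	NONE	0	female	33	African-American
HC08	HC	NONE	0	female	24	Caucasian
HC09	HC	NONE	0	female	24	Caucasian
HC10	HC	NONE	0	male	24	African-American
HC11	HC	NONE	0	male	31	Caucasian
HC12	HC	NONE	0	female	37	African-American
HC13	HC	NONE	0	female	21	African-American
HC14	HC	NONE	0	female	21	Asian
HC15	HC	NONE	0	female	16	Mixed/Other
HC16	HC	NONE	0	female	43	Mixed/Other
HC17	HC	NONE	0	male	22	Caucasian
HC18	HC	NONE	0	female	28	African-American
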