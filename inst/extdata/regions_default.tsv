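region	lo	hi	fixed	default_len	anchor
FW1	1	25	FALSE	25	NA
CDR1	26	32	FALSE	7	31
FW2	33	51	TRUE	19	NA
CDR2	52	56	FALSE	5	54
FW3	57	94	TRUE	38	NA
CDR3	95	102	FALSE	8	100
FW4	103	113	FALSE	11	NA
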