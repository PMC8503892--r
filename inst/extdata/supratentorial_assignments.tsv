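sample_id	label	score	evidence
EPN_ST_01	RELA+	NA	published-label
EPN_ST_02	RELA+	NA	published-label
EPN_ST_03	RELA+	NA	published-label
EPN_ST_04	RELA+	NA	published-label
EPN_ST_05	RELA+	NA	published-label
EPN_ST_06	RELA+	NA	published-label
EPN_ST_07	RELA+	NA	published-label
EPN_ST_08	RELA+	NA	published-label
EPN_ST_09	RELA+	NA	published-label
EPN_ST_10	YAP1+	NA	published-label
EPN_ST_11	MN1	NA	published-label
EPN_ST_12	MN1	NA	published-label
EPN_ST_13	NC	NA	published-label
EPN_ST_14	NC	NA	published-label
EPN_ST_15	NC	NA	published-label
EPN_ST_16	NC	NA	published-label
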