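SYNTH_T_CELL_ACTIVATION	synthetic example set	CD69	IL2RA	TNF	IFNG	GZMB
SYNTH_CHEMOTAXIS	synthetic example set	CXCL9	CXCL10	CXCL11	CCL4	CCL5	CXCR3
SYNTH_EXHAUSTION_PROGRAM	synthetic example set	PDCD1	LAG3	HAVCR2	TIGIT	CTLA4	TOX
SYNTH_HOUSEKEEPING	synthetic example set	GENE0001	GENE0002	GENE0003	GENE0004
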