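label	g_md_pS	baseline
wild-type	10.2	FALSE
Q586R	3.3	TRUE
Q586G	11.7	FALSE
Q586E.0	92.4	FALSE
Q586E.1	19.8	FALSE
Q586E.2	19.8	FALSE
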