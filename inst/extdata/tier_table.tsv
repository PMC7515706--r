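tier	domain	conserved	efficacy	cds	construct	snp	specificity
1	TRUE	TRUE	TRUE	TRUE	TRUE	TRUE	full
2	FALSE	TRUE	TRUE	TRUE	TRUE	TRUE	full
3	FALSE	FALSE	TRUE	TRUE	TRUE	TRUE	full
4	FALSE	FALSE	FALSE	TRUE	TRUE	TRUE	full
5	FALSE	FALSE	FALSE	FALSE	TRUE	TRUE	full
6	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	full
7.1	TRUE	TRUE	TRUE	TRUE	TRUE	TRUE	relaxed
7.2	FALSE	TRUE	TRUE	TRUE	TRUE	TRUE	relaxed
7.3	FALSE	FALSE	TRUE	TRUE	TRUE	TRUE	relaxed
7.4	FALSE	FALSE	FALSE	TRUE	TRUE	TRUE	relaxed
7.5	FALSE	FALSE	FALSE	FALSE	TRUE	TRUE	relaxed
7.6	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	relaxed
8	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	none
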