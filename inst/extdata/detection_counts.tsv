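family	ref_detected	ref_total	ref_pct	germline_all_tissues
L1Hs	817	1528	53.5	167
AluYa5	2933	3918	74.9	653
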