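2026-09-10 23:21:44 marginflow 0.1.0 command: frobnicate 
2026-09-10 23:21:44 marginflow 0.1.0 command: analyze 
2026-09-10 23:22:21 marginflow 0.1.0 command: frobnicate 
2026-09-10 23:22:21 marginflow 0.1.0 command: analyze 
2026-09-10 23:32:11 marginflow 0.1.0 command: frobnicate 
2026-09-10 23:32:11 marginflow 0.1.0 command: analyze 
2026-09-10 23:38:55 marginflow 0.1.0 command: frobnicate 
2026-09-10 23:38:55 marginflow 0.1.0 command: analyze 
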