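bay,survey_days,survey_hours,recording_days,n_individuals_documented
Makako,46,395,565,220
Kealakekua,92,818,484,130
Honaunau,46,412,563,124
Kauhako,92,856,536,85
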