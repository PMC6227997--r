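bay,date,status
Kealakekua,2011-01-01,ABSENT
Kealakekua,2011-01-02,PRESENT
Kealakekua,2011-01-03,ABSENT
Kealakekua,2011-01-04,ABSENT
Kealakekua,2011-01-05,PRESENT
Kealakekua,2011-01-06,ABSENT
Kealakekua,2011-01-07,PRESENT
Kealakekua,2011-01-08,ABSENT
Kealakekua,2011-01-09,ABSENT
Kealakekua,2011-01-10,ABSENT
Makako,2011-01-01,PRESENT
Makako,2011-01-02,ABSENT
Makako,2011-01-03,PRESENT
Makako,2011-01-04,PRESENT
Makako,2011-01-05,PRESENT
Makako,2011-01-06,PRESENT
Makako,2011-01-07,PRESENT
Makako,2011-01-08,PRESENT
Makako,2011-01-09,PRESENT
Makako,2011-01-10,PRESENT
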