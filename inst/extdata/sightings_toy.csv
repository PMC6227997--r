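individual_id,date,bay
A,2011-01-01,Makako
A,2011-01-03,Makako
A,2011-01-05,Makako
A,2011-01-07,Kealakekua
B,2011-01-01,Makako
B,2011-01-05,Makako
C,2011-01-02,Kealakekua
C,2011-01-07,Kealakekua
C,2011-01-09,Makako
D,2011-01-02,Kealakekua
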