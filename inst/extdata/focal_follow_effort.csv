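platform,location,n_follows,hours
LAND,Kealakekua,23,189
LAND,Kauhako,7,38
BOAT,Makako,13,26
BOAT,Kealakekua,10,16
BOAT,Honaunau,5,21
BOAT,Kauhako,10,16
BOAT,OUTSIDE,37,84
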