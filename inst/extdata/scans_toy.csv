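follow_id,timestamp,platform,location,activity,n_boats,n_kayaks,n_swimmers
F01,2011-01-01 08:00,BOAT,Makako,REST,0,0,0
F01,2011-01-01 08:10,BOAT,Makako,REST,0,0,0
F01,2011-01-01 08:20,BOAT,Makako,REST,1,0,0
F01,2011-01-01 08:30,BOAT,Makako,SOCIAL,0,2,3
F01,2011-01-01 08:40,BOAT,OUTSIDE,TRAVEL,0,1,0
F01,2011-01-01 08:50,BOAT,OUTSIDE,TRAVEL,0,0,0
F02,2011-01-02 09:00,LAND,Kealakekua,SOCIAL,0,1,0
F02,2011-01-02 09:10,LAND,Kealakekua,REST,0,0,1
F02,2011-01-02 09:20,LAND,Kealakekua,REST,0,0,0
F02,2011-01-02 09:30,LAND,Kealakekua,SOCIAL,0,0,0
F03,2011-01-03 10:00,BOAT,OUTSIDE,TRAVEL,2,0,1
F03,2011-01-03 10:10,BOAT,OUTSIDE,TRAVEL,0,0,0
F03,2011-01-03 10:20,BOAT,OUTSIDE,SOCIAL,1,1,1
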