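psLayout version 3

match	mis- 	rep. 	N's	Q gap	Q gap	T gap	T gap	strand	Q        	Q   	Q    	Q  	T        	T   	T    	T  	block	blockSizes 	qStarts	 tStarts
     	match	match	   	count	bases	count	bases	      	name     	size	start	end	name     	size	start	end	count
---------------------------------------------------------------------------------------------------------------------------------------------------------------
76	4	0	0	0	0	1	120	+	GENE_A	100	10	90	chr2	50000	1000	1200	2	50,30,	10,60,	1000,1170,
60	0	0	0	0	0	0	0	-	GENE_B	80	10	70	chr3	40000	2000	2060	1	60,	10,	2000,
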