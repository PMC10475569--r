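chrom,pos,ref,alt,group,n_ref_ref,n_het,n_alt_alt
10,17813533,G,T,yellow,0,0,20
10,17813533,G,T,black,40,0,0
10,17813579,C,G,yellow,0,0,20
10,17813579,C,G,black,40,0,0
10,17813659,C,T,yellow,0,0,20
10,17813659,C,T,black,40,0,0
10,17813681,G,A,yellow,0,0,20
10,17813681,G,A,black,40,0,0
10,17813845,C,T,yellow,0,0,20
10,17813845,C,T,black,40,0,0
10,17813883,C,T,yellow,0,0,20
10,17813883,C,T,black,39,1,0
10,17813989,T,C,yellow,0,0,20
10,17813989,T,C,black,40,0,0
10,17814232,C,T,yellow,0,0,20
10,17814232,C,T,black,40,0,0
10,17814486,C,A,yellow,20,0,0
10,17814486,C,A,black,0,1,39
10,17814522,T,A,yellow,0,0,20
10,17814522,T,A,black,40,0,0
10,17816174,T,C,yellow,0,0,20
10,17816174,T,C,black,40,0,0
10,17816775,T,C,yellow,0,0,20
10,17816775,T,C,black,40,0,0
10,17816914,A,G,yellow,20,0,0
10,17816914,A,G,black,0,0,40
10,17817511,C,T,yellow,0,0,20
10,17817511,C,T,black,40,0,0
10,17817645,G,A,yellow,0,0,20
10,17817645,G,A,black,40,0,0
10,17819421,G,A,yellow,0,0,20
10,17819421,G,A,black,40,0,0
10,17819741,T,C,yellow,20,0,0
10,17819741,T,C,black,0,0,40
10,17821300,A,G,yellow,0,0,20
10,17821300,A,G,black,40,0,0
10,17821305,T,G,yellow,0,0,20
10,17821305,T,G,black,40,0,0
10,17821868,C,T,yellow,0,0,20
10,17821868,C,T,black,40,0,0
10,17821942,T,A,yellow,0,0,20
10,17821942,T,A,black,40,0,0
10,17822058,G,A,yellow,0,0,20
10,17822058,G,A,black,40,0,0
10,17822348,A,G,yellow,0,0,20
10,17822348,A,G,black,40,0,0
10,17822368,G,A,yellow,0,0,20
10,17822368,G,A,black,40,0,0
10,17822496,G,A,yellow,0,0,20
10,17822496,G,A,black,40,0,0
10,17822600,T,G,yellow,0,0,20
10,17822600,T,G,black,40,0,0
10,17822617,G,A,yellow,0,0,20
10,17822617,G,A,black,40,0,0
10,17822689,G,T,yellow,0,0,20
10,17822689,G,T,black,40,0,0
10,17822972,C,G,yellow,0,0,20
10,17822972,C,G,black,40,0,0
10,17822994,G,A,yellow,0,0,20
10,17822994,G,A,black,40,0,0
10,17823136,A,G,yellow,0,0,20
10,17823136,A,G,black,40,0,0
10,17823139,C,T,yellow,0,0,20
10,17823139,C,T,black,40,0,0
10,17823565,C,T,yellow,0,0,20
10,17823565,C,T,black,40,0,0
10,17823728,G,A,yellow,0,0,20
10,17823728,G,A,black,40,0,0
10,17823907,C,T,yellow,0,0,20
10,17823907,C,T,black,40,0,0
10,17824027,A,G,yellow,0,0,20
10,17824027,A,G,black,39,1,0
10,17824405,T,C,yellow,0,0,20
10,17824405,T,C,black,40,0,0
10,17825466,G,C,yellow,0,0,20
10,17825466,G,C,black,40,0,0
10,17826419,G,A,yellow,0,0,20
10,17826419,G,A,black,40,0,0
10,17826502,A,G,yellow,20,0,0
10,17826502,A,G,black,0,1,39
10,17827159,C,T,yellow,0,1,19
10,17827159,C,T,black,40,0,0
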