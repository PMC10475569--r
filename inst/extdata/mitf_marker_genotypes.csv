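cohort,population,beak_color,chrom,pos,ref,alt,n_ref_ref,n_het,n_alt_alt
discovery,resequenced yellow,yellow,10,17814522,T,A,0,0,20
discovery,resequenced black,black,10,17814522,T,A,40,0,0
f2,F2 yellow,yellow,10,17814522,T,A,0,2,18
f2,F2 black,black,10,17814522,T,A,10,10,0
breeds,Cherry Valley Duck,yellow,10,17814522,T,A,0,0,30
breeds,Jingding Duck,yellow,10,17814522,T,A,0,0,20
breeds,Ji'an Red Duck,yellow,10,17814522,T,A,0,0,20
breeds,Gaoyou Duck,black,10,17814522,T,A,24,5,0
breeds,Liancheng White Duck,black,10,17814522,T,A,17,13,0
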