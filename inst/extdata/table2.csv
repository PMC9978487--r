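term,region,scenario,mean,se,units
total,global,ssp126,227,90,mmol C m-2 y-1
total,NH,ssp126,88,16,mmol C m-2 y-1
total,NI,ssp126,336,51,mmol C m-2 y-1
total,LL,ssp126,1013,522,mmol C m-2 y-1
total,SI,ssp126,276,148,mmol C m-2 y-1
total,SO,ssp126,43,25,mmol C m-2 y-1
total,global,ssp245,311,93,mmol C m-2 y-1
total,NH,ssp245,103,16,mmol C m-2 y-1
total,NI,ssp245,409,52,mmol C m-2 y-1
total,LL,ssp245,1386,548,mmol C m-2 y-1
total,SI,ssp245,409,153,mmol C m-2 y-1
total,SO,ssp245,77,26,mmol C m-2 y-1
total,global,ssp370,371,97,mmol C m-2 y-1
total,NH,ssp370,106,16,mmol C m-2 y-1
total,NI,ssp370,430,53,mmol C m-2 y-1
total,LL,ssp370,1648,574,mmol C m-2 y-1
total,SI,ssp370,535,159,mmol C m-2 y-1
total,SO,ssp370,114,27,mmol C m-2 y-1
total,global,ssp585,520,102,mmol C m-2 y-1
total,NH,ssp585,180,17,mmol C m-2 y-1
total,NI,ssp585,608,55,mmol C m-2 y-1
total,LL,ssp585,2242,609,mmol C m-2 y-1
total,SI,ssp585,705,168,mmol C m-2 y-1
total,SO,ssp585,154,28,mmol C m-2 y-1
doc_term,global,ssp126,2,36,mmol C m-2 y-1
doc_term,NH,ssp126,0.31,12,mmol C m-2 y-1
doc_term,NI,ssp126,1,23,mmol C m-2 y-1
doc_term,LL,ssp126,2.5,75,mmol C m-2 y-1
doc_term,SI,ssp126,0.98,76,mmol C m-2 y-1
doc_term,SO,ssp126,34,22,mmol C m-2 y-1
doc_term,global,ssp245,2.5,36,mmol C m-2 y-1
doc_term,NH,ssp245,0.28,12,mmol C m-2 y-1
doc_term,NI,ssp245,1,23,mmol C m-2 y-1
doc_term,LL,ssp245,3,75,mmol C m-2 y-1
doc_term,SI,ssp245,1.7,74,mmol C m-2 y-1
doc_term,SO,ssp245,58,22,mmol C m-2 y-1
doc_term,global,ssp370,3,35,mmol C m-2 y-1
doc_term,NH,ssp370,0.27,12,mmol C m-2 y-1
doc_term,NI,ssp370,1.1,23,mmol C m-2 y-1
doc_term,LL,ssp370,3.3,74,mmol C m-2 y-1
doc_term,SI,ssp370,2.5,72,mmol C m-2 y-1
doc_term,SO,ssp370,84,23,mmol C m-2 y-1
doc_term,global,ssp585,3.9,35,mmol C m-2 y-1
doc_term,NH,ssp585,0.29,11,mmol C m-2 y-1
doc_term,NI,ssp585,1.4,23,mmol C m-2 y-1
doc_term,LL,ssp585,4.6,74,mmol C m-2 y-1
doc_term,SI,ssp585,3.3,70,mmol C m-2 y-1
doc_term,SO,ssp585,109,22,mmol C m-2 y-1
temp_term,global,ssp126,225,78,mmol C m-2 y-1
temp_term,NH,ssp126,88,10,mmol C m-2 y-1
temp_term,NI,ssp126,335,44,mmol C m-2 y-1
temp_term,LL,ssp126,1010,513,mmol C m-2 y-1
temp_term,SI,ssp126,275,122,mmol C m-2 y-1
temp_term,SO,ssp126,7.7,3.6,mmol C m-2 y-1
temp_term,global,ssp245,308,82,mmol C m-2 y-1
temp_term,NH,ssp245,103,10,mmol C m-2 y-1
temp_term,NI,ssp245,407,45,mmol C m-2 y-1
temp_term,LL,ssp245,1382,538,mmol C m-2 y-1
temp_term,SI,ssp245,407,129,mmol C m-2 y-1
temp_term,SO,ssp245,14,3.8,mmol C m-2 y-1
temp_term,global,ssp370,368,86,mmol C m-2 y-1
temp_term,NH,ssp370,106,11,mmol C m-2 y-1
temp_term,NI,ssp370,428,46,mmol C m-2 y-1
temp_term,LL,ssp370,1643,564,mmol C m-2 y-1
temp_term,SI,ssp370,532,136,mmol C m-2 y-1
temp_term,SO,ssp370,20,4.2,mmol C m-2 y-1
temp_term,global,ssp585,515,92,mmol C m-2 y-1
temp_term,NH,ssp585,179,12,mmol C m-2 y-1
temp_term,NI,ssp585,606,47,mmol C m-2 y-1
temp_term,LL,ssp585,2235,600,mmol C m-2 y-1
temp_term,SI,ssp585,701,147,mmol C m-2 y-1
temp_term,SO,ssp585,28,4.7,mmol C m-2 y-1
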