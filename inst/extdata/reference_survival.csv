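herd,interval,year,season,estimate,fixed
A,1,2007,july,0.988,FALSE
A,2,2007,autumn,0.988,FALSE
A,3,2008,spring,0.989,FALSE
A,4,2008,july,1,TRUE
A,5,2008,autumn,0.98,FALSE
A,6,2009,spring,0.985,FALSE
A,7,2009,july,1,TRUE
A,8,2009,autumn,0.937,FALSE
A,9,2010,spring,0.975,FALSE
A,10,2010,july,0.962,FALSE
A,11,2010,autumn,0.994,FALSE
A,12,2011,spring,0.949,FALSE
A,13,2011,july,0.994,FALSE
A,14,2011,autumn,0.945,FALSE
A,15,2012,spring,0.977,FALSE
A,16,2012,july,1,TRUE
A,17,2012,autumn,1,TRUE
B,1,2007,july,1,TRUE
B,2,2007,autumn,1,TRUE
B,3,2008,spring,0.958,FALSE
B,4,2008,july,1,TRUE
B,5,2008,autumn,1,TRUE
B,6,2009,spring,0.83,FALSE
B,7,2009,july,1,TRUE
B,8,2009,autumn,0.965,FALSE
B,9,2010,spring,0.793,FALSE
B,10,2010,july,1,TRUE
B,11,2010,autumn,0.884,FALSE
B,12,2011,spring,0.946,FALSE
B,13,2011,july,1,TRUE
B,14,2011,autumn,0.848,FALSE
B,15,2012,spring,0.868,FALSE
B,16,2012,july,1,TRUE
B,17,2012,autumn,1,TRUE
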