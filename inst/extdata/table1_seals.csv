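sdr_id,sdr_type,sex,std_length_cm,girth_axillary_cm,girth_max_cm,date_captured,date_entered_bering,date_last_location,duration_days,days_with_location,bering_location_days,used_in_habitat_analysis
53604,SPLASH,F,NA,NA,NA,5-Oct-04,n/a,1-Feb-05,120,90,0,
53605,SPLASH,F,NA,NA,NA,11-Oct-04,n/a,2-Dec-04,53,49,0,
53606,SPLASH,M,148,113,123,24-Sep-05,10-Nov-05,1-Apr-06,190,157,141,X
53607,SPLASH,F,141,97,110,24-Sep-05,16-Nov-05,8-Feb-06,138,105,84,X
53609,SPLASH,M,140,123,122,26-Sep-05,n/a,5-Jun-06,253,149,0,
53608,SPLASH,M,142,NA,NA,30-Sep-05,9-Nov-05,26-Nov-05,58,55,18,X
53610,SPLASH,M,166,NA,NA,1-Oct-05,21-Dec-05,30-Apr-06,212,176,109,X
53611,SPLASH,M,141,NA,NA,2-Oct-05,2-Dec-05,15-Jan-06,106,84,33,X
59971,SPLASH,F,143,115,NA,2-Oct-05,2-Dec-05,27-Dec-05,87,81,24,X
59970,SPLASH,M,129,NA,NA,3-Oct-05,n/a,20-Apr-06,200,170,0,
59972,SPLASH,F,149,110,115,4-Oct-05,9-Nov-05,30-Mar-06,178,176,141,X
59968,SPLASH,F,135,NA,NA,7-Oct-05,27-Oct-05,4-May-06,210,168,148,X
59969,SPLASH,M,145,121,125,7-Oct-05,22-Oct-05,19-Nov-05,44,39,25,X
59973,SPLASH,F,134,NA,NA,7-Oct-05,n/a,7-Jan-06,93,77,0,
59974,SPLASH,F,140,96,106,7-Oct-05,7-Nov-05,22-Feb-06,139,95,67,X
59976,SPLASH,M,157,129,131,7-Oct-05,20-Oct-05,2-Feb-06,119,82,66,X
59967,SPLASH,F,126,NA,NA,11-Oct-05,n/a,15-Oct-05,5,5,0,
58069,SPLASH,F,150,113,124,3-Oct-06,21-Nov-06,26-May-07,236,216,172,X
70413,CTD,M,138,102,118,6-Oct-06,n/a,9-Oct-06,4,2,0,
58059,SPLASH,M,134,102,114,7-Oct-06,11-Nov-06,4-May-07,210,190,162,X
70414,CTD,M,136,108,114,7-Oct-06,n/a,12-Oct-06,5,5,0,
70415,CTD,F,139,108,120,7-Oct-06,n/a,26-Oct-06,19,14,0,
70416,CTD,F,144,118,138,7-Oct-06,8-Nov-06,18-Dec-06,73,57,28,X
70417,CTD,M,151,120,133,7-Oct-06,7-Dec-06,31-Dec-06,86,62,22,X
58060,SPLASH,F,137,116,128,20-Oct-06,12-Nov-06,18-Jan-07,91,88,68,X
65914,SPLASH,M,148,100,109,22-Oct-06,6-Nov-06,22-Dec-06,62,60,46,X
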