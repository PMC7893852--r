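section,province,group,variable,level,count,denom,printed_pct
cases,BC,emr_only,frail_cases,identified,91,4978,1.8
cases,BC,admin_only,frail_cases,identified,517,4978,10.4
cases,BC,both,frail_cases,identified,70,4978,1.4
cases,MB,emr_only,frail_cases,identified,1589,28685,5.5
cases,MB,admin_only,frail_cases,identified,1821,28685,6.3
cases,MB,both,frail_cases,identified,307,28685,1.1
characteristics,BC,emr_only,age_band,65-74,27,91,29.7
characteristics,BC,emr_only,age_band,75-84,35,91,38.5
characteristics,BC,emr_only,age_band,85+,29,91,31.9
characteristics,BC,emr_only,sex,female,55,91,60.4
characteristics,BC,emr_only,sex,male,36,91,39.6
characteristics,BC,emr_only,income,high,58,91,63.7
characteristics,BC,emr_only,income,low,33,91,36.3
characteristics,BC,emr_only,residence,rural,35,91,38.5
characteristics,BC,emr_only,residence,urban,56,91,61.5
characteristics,BC,emr_only,comorb_band_admin,0-1,20,91,22.0
characteristics,BC,emr_only,comorb_band_admin,2,46,91,50.5
characteristics,BC,emr_only,comorb_band_admin,3+,25,91,27.5
characteristics,BC,emr_only,comorb_band_emr,0-1,18,91,19.8
characteristics,BC,emr_only,comorb_band_emr,2,31,91,34.1
characteristics,BC,emr_only,comorb_band_emr,3+,42,91,46.2
characteristics,BC,admin_only,age_band,65-74,122,517,23.6
characteristics,BC,admin_only,age_band,75-84,185,517,35.8
characteristics,BC,admin_only,age_band,85+,210,517,40.6
characteristics,BC,admin_only,sex,female,300,517,58.0
characteristics,BC,admin_only,sex,male,217,517,42.0
characteristics,BC,both,age_band,65-74,5,70,7.1
characteristics,BC,both,age_band,75-84,20,70,28.6
characteristics,BC,both,age_band,85+,45,70,64.3
characteristics,BC,both,sex,female,51,70,72.9
characteristics,BC,both,sex,male,19,70,27.1
characteristics,BC,both,income,high,41,70,58.6
characteristics,BC,both,income,low,29,70,41.4
characteristics,BC,both,residence,rural,26,70,37.1
characteristics,BC,both,residence,urban,44,70,62.9
characteristics,MB,emr_only,age_band,65-74,519,1589,32.7
characteristics,MB,emr_only,age_band,75-84,610,1589,38.4
characteristics,MB,emr_only,age_band,85+,460,1589,28.9
characteristics,MB,emr_only,sex,female,1006,1589,63.3
characteristics,MB,emr_only,sex,male,583,1589,36.7
characteristics,MB,emr_only,income,high,810,1576,51.4
characteristics,MB,emr_only,income,low,766,1576,48.6
characteristics,MB,emr_only,residence,rural,692,1589,43.5
characteristics,MB,emr_only,residence,urban,897,1589,56.5
characteristics,MB,admin_only,age_band,65-74,270,1821,14.8
characteristics,MB,admin_only,age_band,75-84,610,1821,33.5
characteristics,MB,admin_only,sex,female,1163,1821,63.9
characteristics,MB,admin_only,sex,male,658,1821,36.1
characteristics,MB,admin_only,income,high,714,1494,47.8
characteristics,MB,admin_only,income,low,780,1494,52.2
characteristics,MB,admin_only,residence,rural,548,1821,30.1
characteristics,MB,admin_only,residence,urban,1273,1821,69.9
characteristics,MB,both,age_band,65-74,42,307,13.7
characteristics,MB,both,age_band,75-84,94,307,30.6
characteristics,MB,both,age_band,85+,171,307,55.7
characteristics,MB,both,sex,female,196,307,63.8
characteristics,MB,both,sex,male,111,307,36.2
characteristics,MB,both,income,high,142,281,50.5
characteristics,MB,both,income,low,139,281,49.5
characteristics,MB,both,residence,rural,105,307,34.2
characteristics,MB,both,residence,urban,202,307,65.8
outcomes,BC,emr_only,polypharmacy,yes,80,91,87.9
outcomes,BC,emr_only,died_next_year,yes,6,91,6.6
outcomes,BC,admin_only,polypharmacy,yes,311,387,80.4
outcomes,BC,admin_only,died_next_year,yes,77,387,19.9
outcomes,BC,both,polypharmacy,yes,42,56,75.0
outcomes,BC,both,died_next_year,yes,15,56,26.8
outcomes,MB,emr_only,polypharmacy,yes,1221,1553,78.6
outcomes,MB,emr_only,died_next_year,yes,36,1553,2.3
outcomes,MB,admin_only,polypharmacy,yes,649,1319,49.2
outcomes,MB,admin_only,died_next_year,yes,136,1319,10.3
outcomes,MB,both,polypharmacy,yes,144,216,66.7
outcomes,MB,both,died_next_year,yes,30,216,13.9
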