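"session_id","phase","confidence_anatomy","confidence_approach","tlx_mental","tlx_physical","tlx_time","tlx_performance","tlx_effort","tlx_frustration","conference_mental_demand"
"s01","pre",3,2,NA,NA,NA,NA,NA,NA,NA
"s02","pre",4,5,NA,NA,NA,NA,NA,NA,NA
"s03","pre",4,5,NA,NA,NA,NA,NA,NA,NA
"s04","pre",3,3,NA,NA,NA,NA,NA,NA,NA
"s05","pre",4,4,NA,NA,NA,NA,NA,NA,NA
"s06","pre",4,4,NA,NA,NA,NA,NA,NA,NA
"s07","pre",3,4,NA,NA,NA,NA,NA,NA,NA
"s08","pre",4,3,NA,NA,NA,NA,NA,NA,NA
"s09","pre",4,4,NA,NA,NA,NA,NA,NA,NA
"s10","pre",3,4,NA,NA,NA,NA,NA,NA,NA
"s01","post",3,2,5,3,1,10,4,1,NA
"s02","post",4,5,3,1,2,10,3,1,NA
"s03","post",4,5,3,4,1,10,4,2,NA
"s04","post",4,3,4,4,1,10,3,4,5
"s05","post",5,4,4,3,1,8,4,1,6
"s06","post",5,4,3,3,2,10,3,1,5
"s07","post",4,4,4,4,1,9,4,2,6
"s08","post",5,4,4,3,1,10,3,1,6
"s09","post",5,4,4,3,1,10,5,1,5
"s10","post",4,4,2,1,2,8,1,1,6
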