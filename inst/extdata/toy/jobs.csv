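job_id,participant_id,slot,title,description,start_year,end_year
J01,T001,recent,welder,welds metal parts in a plant,1990,2013
J02,T001,previous,machinist,machines metal parts,1975,1990
J03,T002,recent,secretary,worked in a military facility,2000,2016
J04,T002,longest1,teacher,teaches school classes,1985,2000
J05,T003,recent,truck driver,drives a diesel truck,1995,2017
J06,T004,recent,registered nurse,provides patient care,1980,2014
J07,T004,previous,office clerk,files documents,1978,1980
J08,T005,recent,farm worker,applies pesticides on a farm,1992,2015
J09,T006,recent,accountant,prepares accounts,2014,2014
J10,T006,previous,retail salesperson,sells goods in a store,1998,2013
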