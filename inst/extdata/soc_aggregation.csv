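"soc_code","agg_code","agg_label"
"11-1021","AG-11","Manager, general"
"11-9199","AG-11","Manager, general"
"13-2011","AG-13","Analyst, financial"
"15-1132","AG-15","Computing professional"
"17-2112","AG-17","Engineer"
"17-2141","AG-17","Engineer"
"25-2021","AG-25","Teacher"
"29-1141","AG-29","Healthcare practitioner"
"29-2034","AG-29","Healthcare practitioner"
"31-1014","AG-31","Healthcare support"
"35-2014","AG-35","Food preparation"
"37-2011","AG-37","Cleaning and grounds"
"41-2031","AG-41","Sales"
"41-4012","AG-41","Sales"
"43-6014","AG-43","Office and administrative"
"43-9061","AG-43","Office and administrative"
"45-2092","AG-45","Farming and forestry"
"47-2111","AG-47","Trades, electrical and sheet metal"
"47-2152","AG-47","Trades, plumbing"
"49-3023","AG-49","Mechanic, vehicle"
"49-9041","AG-49","Mechanic, industrial"
"51-4121","AG-51","Operator, welding and metals"
"51-9011","AG-51","Operator, chemical"
"51-4041","AG-51","Operator, welding and metals"
"53-3032","AG-53","Transportation"
"55-3019","AG-55","Military"
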