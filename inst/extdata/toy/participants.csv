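participant_id,status,age_at_reference,sex,military,education,onset_year,consent_year
T001,case,64.2,male,neither,hs_or_less,2014,2015
T002,case,58.0,female,enlisted,some_postsecondary,2016,2017
T003,case,71.5,male,missing,bachelor,,2018
T004,control,62.1,female,neither,graduate,,2015
T005,control,55.9,male,neither,bachelor,,2016
T006,case,49.3,female,neither,some_postsecondary,2013,2014
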