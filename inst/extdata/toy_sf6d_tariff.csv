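"dimension","level","decrement"
"physical_functioning",1,0
"physical_functioning",2,0.05
"physical_functioning",3,0.1
"physical_functioning",4,0.15
"physical_functioning",5,0.2
"role_limitation",1,0
"role_limitation",2,0.05
"role_limitation",3,0.1
"role_limitation",4,0.15
"role_limitation",5,0.2
"social_functioning",1,0
"social_functioning",2,0.05
"social_functioning",3,0.1
"social_functioning",4,0.15
"social_functioning",5,0.2
"pain",1,0
"pain",2,0.05
"pain",3,0.1
"pain",4,0.15
"pain",5,0.2
"mental_health",1,0
"mental_health",2,0.05
"mental_health",3,0.1
"mental_health",4,0.15
"mental_health",5,0.2
"vitality",1,0
"vitality",2,0.05
"vitality",3,0.1
"vitality",4,0.15
"vitality",5,0.2
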