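"column","type","description"
"substance","character","analyte name"
"matrix","character","one of plasma, urine, faeces, hair"
"animal_id","character","animal identifier, unique within group"
"group","character","dose group: vehicle, half, one, two"
"day","integer","study day of collection (0 = pre-dose)"
"time_h","numeric","hours post-dose within the day (0 outside the day-7 grid)"
"value","numeric","concentration, ng/mL (liquids) or pg/mg (solids); 0 when censored"
"censored","logical","TRUE when below the limit of detection"
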