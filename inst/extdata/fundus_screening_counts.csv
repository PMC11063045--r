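model,class,correct,total
RETFound,AMD,218,287
RETFound,DR,321,337
RETFound,PM,151,151
RETFound,normal,1031,1115
Model S,AMD,176,287
Model S,DR,266,337
Model S,PM,90,151
Model S,normal,866,1115
Model Y,AMD,170,287
Model Y,DR,240,337
Model Y,PM,109,151
Model Y,normal,821,1115
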