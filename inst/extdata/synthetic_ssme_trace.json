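{"sensor_id":"sensor-1","phases":[{"phase":"internal_1","t_start":0,"t_end":0.5},{"phase":"external","t_start":0.5,"t_end":1.5},{"phase":"internal_2","t_start":1.5,"t_end":2}],"condition":{"label":"no_gradient","pH_in":7.3,"pH_out":7,"drug_in_uM":8,"drug_out_uM":8,"drug_charge":0}}
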