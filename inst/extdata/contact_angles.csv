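surface,liquid,theta_mean_deg,theta_sd_deg,n
eucalyptus,water,142.6,6.7,30
eucalyptus,glycerol,136.5,11.2,30
eucalyptus,diiodomethane,84.0,7.0,30
pepper,water,83.4,4.7,30
pepper,glycerol,68.6,9.2,30
pepper,diiodomethane,60.8,6.2,30
peach,water,134.2,7.0,30
peach,glycerol,130.9,7.0,30
peach,diiodomethane,55.7,3.9,30
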