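species,radius_um,phase,q_exu,u_max,km_uptake,bulk_doc,bulk_nitrate,provenance
Synechococcus bacillaris,1.0,exponential,15,10,1.0,0.005,882,literature default (calibrated)
Synechococcus bacillaris,1.0,stationary,24,10,1.0,0.008,0,literature default (calibrated)
Micromonas pusilla,0.8,exponential,10,8,0.8,0.007,882,literature default (calibrated)
Micromonas pusilla,0.8,stationary,16,8,0.8,0.0112,0,literature default (calibrated)
Phaeodactylum tricornutum,2.0,exponential,60,60,2.0,0.009,882,literature default (calibrated)
Phaeodactylum tricornutum,2.0,stationary,96,60,2.0,0.0144,0,literature default (calibrated)
Thalassiosira weissflogii,6.0,exponential,500,300,1.5,0.020,882,literature default (calibrated)
Thalassiosira weissflogii,6.0,stationary,800,300,1.5,0.032,0,literature default (calibrated)
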