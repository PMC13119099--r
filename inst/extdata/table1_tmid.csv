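model,concentration_M,value
gompertz,0,121.7
gompertz,0.15,119.8
gompertz,0.3,124.4
gompertz,0.45,140.2
gompertz,0.6,153.3
gompertz,0.75,159.6
gompertz,0.9,199.8
gompertz,1.05,215.7
gompertz,1.2,260.7
gompertz,1.35,275.0
gompertz,1.5,271.5
logit,0,123.5
logit,0.15,122.8
logit,0.3,130.2
logit,0.45,152.8
logit,0.6,165.8
logit,0.75,172.2
logit,0.9,207.7
logit,1.05,228.5
logit,1.2,266.5
logit,1.35,282.1
logit,1.5,277.7
dose_response,0,122.2
dose_response,0.15,120.3
dose_response,0.3,125.0
dose_response,0.45,140.9
dose_response,0.6,154.2
dose_response,0.75,160.5
dose_response,0.9,201.1
dose_response,1.05,217.0
dose_response,1.2,262.9
dose_response,1.35,276.7
dose_response,1.5,273.5
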