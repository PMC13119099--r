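model,concentration_M,value
gompertz,0,0.043
gompertz,0.15,0.036
gompertz,0.3,0.029
gompertz,0.45,0.023
gompertz,0.6,0.016
gompertz,0.75,0.016
gompertz,0.9,0.015
gompertz,1.05,0.014
gompertz,1.2,0.010
gompertz,1.35,0.014
gompertz,1.5,0.011
logit,0,0.106
logit,0.15,0.088
logit,0.3,0.073
logit,0.45,0.055
logit,0.6,0.038
logit,0.75,0.037
logit,0.9,0.052
logit,1.05,0.045
logit,1.2,0.040
logit,1.35,0.056
logit,1.5,0.044
dose_response,0,20.98
dose_response,0.15,16.91
dose_response,0.3,13.98
dose_response,0.45,12.27
dose_response,0.6,9.25
dose_response,0.75,10.12
dose_response,0.9,12.07
dose_response,1.05,11.45
dose_response,1.2,9.97
dose_response,1.35,14.94
dose_response,1.5,11.95
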