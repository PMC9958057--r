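index,slope,intercept
RRM1,664,4
RRM2,1133,15
RRHM1,4684,60
RRHM2,14335,431
RRF,2418,30
RRABC,62.6009177191,-0.1082
RRGA,93.9919881117,1.9836
RRR_0.5,326.571942,2.00803434
RRR_-1,8.8986,-0.0819
RRR_-0.5,26.1823,-0.0075
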