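degree,property,index,a2,a1,gamma
1,BP,RRR_-1,0,129,-75.26
1,LogP,RRR_-1,0,1.228,0.296
1,CT,RRGA,0,16.62,291.4
1,GE,RRHM1,0,0.9654,26.46
1,PI,RRABC,0,1.63,1.197
1,HL,RRF,0,0.01448,-0.03858
1,CP,RRR_-1,0,-6.6085,54.162
1,CV,RRR_-0.5,0,73.21,46.92
1,EM,RRR_-0.5,0,25.23,3.109
1,HAC,RRR_-0.5,0,2.024,-0.022
1,MR,RRR_-0.5,0,8.699,-0.6273
1,MW,RRR_-0.5,0,25.25,3.143
2,BP,RRR_-1,-10.47,202.4,-192.6
2,LogP,RRR_-1,-0.0407,1.513,-0.1598
2,CT,RRGA,-0.3939,31.57,-166.2
2,GE,RRHM1,0.000047,0.9208,35.4
2,PI,RRABC,-0.004891,1.761,0.4245
2,HL,RRF,8.815e-8,0.01444,-0.03427
2,CP,RRR_-0.5,0.1774,-5.46,62.12
2,CV,RRR_-0.5,-0.2004,76.46,35.08
2,EM,RRR_-0.5,-0.05377,26.1,-0.06767
2,HAC,RRR_-0.5,-0.003732,2.084,-0.2424
2,MR,RRR_-0.5,-0.0148,8.939,-1.503
2,MW,RRR_-0.5,-0.0085,3.042,-1.157
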