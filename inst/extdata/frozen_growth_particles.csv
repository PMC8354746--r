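id,x,y,vx,vy,rho,p,mass,phase,streak,mean_speed
1,0.250000000000,0.250000000000,0,0,1000,0,2.5,LIVE_CORAL,0,NA
2,0.250000000000,0.300000000000,0,0,1000,0,2.5,FLUID,0,0.020
3,0.299497474683,0.299497474683,0,0,1000,0,2.5,FLUID,0,0.045
4,0.330000000000,0.250000000000,0,0,1000,0,2.5,FLUID,0,0.070
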