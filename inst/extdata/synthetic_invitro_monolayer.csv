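source,dose,metric,time,mean,dispersion
invitro_monolayer,0,gammah2ax_pct,0,2.1,0.8
invitro_monolayer,0,gammah2ax_pct,24,2.4,0.9
invitro_monolayer,0,gammah2ax_pct,48,2.2,0.7
invitro_monolayer,0,gammah2ax_pct,72,2.5,1.0
invitro_monolayer,0.3,gammah2ax_pct,0,2.2,0.8
invitro_monolayer,0.3,gammah2ax_pct,24,6.5,1.5
invitro_monolayer,0.3,gammah2ax_pct,48,7.1,1.6
invitro_monolayer,0.3,gammah2ax_pct,72,6.8,1.4
invitro_monolayer,1,gammah2ax_pct,0,2.0,0.7
invitro_monolayer,1,gammah2ax_pct,24,28.0,4.0
invitro_monolayer,1,gammah2ax_pct,48,34.0,4.5
invitro_monolayer,1,gammah2ax_pct,72,36.0,5.0
invitro_monolayer,3,gammah2ax_pct,0,2.3,0.8
invitro_monolayer,3,gammah2ax_pct,24,48.0,6.0
invitro_monolayer,3,gammah2ax_pct,48,58.0,6.5
invitro_monolayer,3,gammah2ax_pct,72,61.0,7.0
invitro_monolayer,10,gammah2ax_pct,0,2.1,0.8
invitro_monolayer,10,gammah2ax_pct,24,60.0,7.0
invitro_monolayer,10,gammah2ax_pct,48,70.0,7.5
invitro_monolayer,10,gammah2ax_pct,72,73.0,8.0
invitro_monolayer,0,total,0,1020,120
invitro_monolayer,0,total,24,2050,260
invitro_monolayer,0,total,48,4100,480
invitro_monolayer,0,total,72,8600,950
invitro_monolayer,1,total,0,1010,110
invitro_monolayer,1,total,24,1700,210
invitro_monolayer,1,total,48,2500,320
invitro_monolayer,1,total,72,3300,420
invitro_monolayer,10,total,0,1005,115
invitro_monolayer,10,total,24,1300,170
invitro_monolayer,10,total,48,1450,200
invitro_monolayer,10,total,72,1500,210
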