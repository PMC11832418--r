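site,latitude,longitude,elevation_masl,mat,t_day,t_night,mat_p10,mat_p90,map_mm
14C,5.513,-75.678,2516,13.78,16.1,12.6,11.6,18.4,2774
22C,5.541,-75.685,1357,22.14,22.5,19.6,18.3,26.4,2045
26C,6.844,-75.810,736,25.58,27.1,22.7,20.7,32.3,2298
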