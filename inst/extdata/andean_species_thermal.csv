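species,family,group,n_records,t_opt,t_opt_sd,mean_tmin,tmin_sd,mean_tmax,tmax_sd,thermal_range_printed,t_sd,cold_p10,cold_p25,hot_p75,hot_p90,alt_min,alt_max,wood_density
Inga spectabilis,Fabaceae,lowland,314,25.1,2.24,19.5,2.5,30.1,2.4,11.1,2.2,15.9,17.8,32.3,34.2,0,1500,0.58
Inga ingoides,Fabaceae,lowland,295,24.7,2.6,17.7,3.5,31.1,2.6,14.9,2.6,13.9,15.7,32.7,33.3,0,2000,0.49
Inga marginata,Fabaceae,lowland,856,22.9,3.3,15.3,5.1,30.3,2.7,15.2,3.4,8.2,10.1,31.9,34.7,0,2000,0.58
Inga densiflora,Fabaceae,lowland,302,22.4,3.3,16.8,3.2,28.3,3.6,11.8,3.3,12.3,14.6,31.2,32.3,500,2500,0.58
Miconia theizans,Melastomataceae,montane,733,16.9,3.7,10.3,4.1,23.1,4.1,14.1,3.7,5.3,7.1,26.5,28.4,500,3000,0.62
Ilex laurina,Aquifoliaceae,montane,123,16.7,3.2,11.3,3.2,22.1,3.6,10.5,3.2,7.3,9.9,24.3,26.2,1500,2500,0.55
Guatteria lehmannii,Annonaceae,montane,22,16.5,1.4,11.8,1.2,21.3,1.6,10.1,1.4,10.4,10.9,22.2,23.3,1500,2500,0.56
Hieronyma antioquensis,Phyllanthaceae,montane,75,16.4,2.9,11.7,2.9,21.2,3.1,9.0,3.0,9.9,10.3,21.3,24.0,2000,2500,0.63
Andesanthus lepidotus,Melastomataceae,montane,1307,15.7,3.1,10.6,3.3,20.9,3.2,11.9,3.1,6.26,7.8,22.7,25.0,1000,3500,0.63
Clethra fagifolia,Clethraceae,montane,470,15.6,2.3,10.6,2.4,20.8,2.5,10.4,2.3,7.3,10.0,21.8,23.9,500,3500,0.48
Chrysochlamys colombiana,Clusiaceae,montane,88,15.6,2.0,10.6,2.0,20.6,2.2,10.0,2.0,8.4,9.3,22.3,22.9,500,3000,0.43
Quercus humboldtii,Fagaceae,montane,701,15.4,1.9,11.0,2.7,20.1,1.5,9.4,3.3,7.4,11.0,21.2,22.5,1500,3500,0.69
Weinmannia pubescens,Cunoniaceae,montane,521,14.8,1.9,9.9,1.9,19.7,2.3,10.6,1.9,7.5,9.4,20.6,22.6,1500,3000,0.50
Clusia multiflora,Clusiaceae,montane,1040,14.7,3.1,9.6,3.3,19.8,3.3,12.0,3.1,5.0,7.1,20.8,24.1,1000,3500,0.56
Clusia ducu,Clusiaceae,montane,111,13.5,1.5,7.3,1.6,18.7,1.7,12.0,2.2,6.2,6.6,19.0,20.9,1500,3000,0.56
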