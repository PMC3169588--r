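# Physico-chemical characteristics and land use of the 24 soils used for the
# ecological validation of the FR1/FF390 qPCR assay (printed values; BD =
# below detection, stored as NA). Units: corg, n g/kg; caco3 g/kg; p g/kg;
# k %; cn unitless.
sample,corg,n,caco3,p,k,ph,texture,cn,land_use
634,19.0,1.8,190.0,0.1,0.5,8.3,Clay loam,10.6,Cropland
750,26.4,2.8,77.6,0.04,1.6,8.0,Clay,9.4,Cropland
854,10.5,0.9,NA,0.08,0.5,6.7,Loam,11.5,Cropland
914,34.4,3.6,56.8,0.1,1.5,7.9,Silt Clay,9.5,Cropland
917,18.8,1.8,NA,0.07,1.6,7.0,Silt Clay Loam,10.3,Cropland
968,11.5,1.2,NA,0.13,1.1,7.0,Silt Clay Loam,9.3,Cropland
1220,9.8,1.0,NA,0.04,3.5,5.9,Loamy Sand,9.9,Cropland
1224,25.6,2.5,6.0,0.03,1.7,7.8,Clay,10.1,Cropland
633,32.8,2.5,39.9,NA,0.4,7.7,Clay,13.0,Forest
693,24.3,1.6,NA,0.02,0.7,4.6,Loam,15.2,Forest
807,26.1,1.5,NA,NA,1.2,5.4,Silt Clay Loam,17.8,Forest
810,42.6,3.0,41.2,0.01,1.2,7.7,Silt Clay,14.3,Forest
857,85.4,6.0,239.0,0.02,0.7,8.0,Silt Clay Loam,14.3,Forest
910,99.5,6.4,47.2,0.02,1.2,7.4,Clay,15.5,Forest
1004,56.8,4.2,130.0,NA,1.4,7.8,Clay,13.6,Forest
1053,42.8,2.8,NA,0.02,2.4,5.0,Loam,15.1,Forest
907,25.0,2.4,NA,0.03,0.9,5.9,Loam,10.3,Grassland
963,23.7,2.3,NA,0.02,2.5,5.6,Loam,10.4,Grassland
965,42.8,4.5,NA,0.02,2.0,6.8,Silt Clay,9.4,Grassland
1095,29.2,2.9,1.3,0.02,1.8,6.9,Clay,10.0,Grassland
1099,21.8,2.1,106,0.04,2.0,8.1,Clay,10.2,Grassland
1146,9.9,0.9,NA,0.04,1.0,6.1,Silt Loam,10.6,Grassland
1182,17.1,1.9,NA,0.04,3.7,5.5,Sandy Loam,8.9,Grassland
1305,18.3,1.8,NA,0.02,3.5,6.5,Loam,10.3,Grassland
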