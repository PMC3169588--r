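# Physico-chemical characteristics of the 5 soils used for the in-vitro
# validation of the FR1/FF390 primer set (printed values; BD stored as NA).
sample,corg,n,caco3,p,k,ph,texture,cn
858,15.0,1.6,NA,0.08,1.5,7.1,Silt Clay,9.4
1012,9.7,1.1,NA,0.10,1.1,7.1,Silt Loam,8.9
1051,26.2,2.5,NA,0.04,3.6,5.4,Sandy Loam,10.4
1101,8.1,0.8,NA,0.09,1.6,6.4,Silt Loam,9.8
1143,60.0,3.0,NA,0.03,3.3,4.3,Sandy Loam,20.3
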