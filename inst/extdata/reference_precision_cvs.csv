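analyte,range,study,cv,sd
rbc,3.0-4.0,repeatability,4.15,0.152
rbc,4.0-4.5,repeatability,0.32,0.020
rbc,4.0-5.0,repeatability,3.61,0.245
rbc,5.0-6.0,repeatability,3.04,0.156
rbc,3.0-4.0,reproducibility,4.10,0.148
rbc,4.0-4.5,reproducibility,2.77,0.131
rbc,4.0-5.0,reproducibility,2.99,0.192
rbc,5.0-6.0,reproducibility,3.70,0.390
wbc,1.0-2.5,repeatability,10.97,0.306
wbc,2.5-4.5,repeatability,5.64,0.412
wbc,4.5-6.0,repeatability,5.38,0.225
wbc,6.0-7.5,repeatability,6.90,0.278
wbc,1.0-2.5,reproducibility,9.33,0.307
wbc,2.5-4.5,reproducibility,5.83,0.200
wbc,4.5-6.0,reproducibility,6.55,0.449
wbc,6.0-7.5,reproducibility,5.17,0.244
plt,50-90,repeatability,7.24,7.0
plt,90-150,repeatability,5.78,20.5
plt,150-250,repeatability,6.50,21.9
plt,250-400,repeatability,8.66,19.15
plt,50-90,reproducibility,7.70,10.5
plt,90-150,reproducibility,8.93,20.3
plt,150-250,reproducibility,8.80,24.3
plt,250-400,reproducibility,11.70,20.2
hb,4.0-8.0,repeatability,1.3,0.206
hb,8.1-12.9,repeatability,2.1,0.395
hb,13.0-15.9,repeatability,1.6,0.289
hb,16.0-19.0,repeatability,1.9,0.277
hb,4.0-8.0,reproducibility,2.0,0.215
hb,8.1-12.9,reproducibility,1.7,0.301
hb,13.0-15.9,reproducibility,1.0,0.190
hb,16.0-19.0,reproducibility,1.5,0.310
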