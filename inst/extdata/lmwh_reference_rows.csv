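stratum,term,level,a,drug_total,n_total,ror,ror_lo,ror_hi,prr,prr_lo,prr_hi,chi2,ic,ic025,ebgm,ebgm05
overall,anti factor X antibody positive,PT,6,61949,52373206,506.70,184.15,1394.23,506.65,184.14,1394.01,1892.46,8.31,1.48,317.03,115.22
overall,heparin-induced thrombocytopenia test positive,PT,19,61949,52373206,263.10,157.20,440.33,263.02,157.17,440.14,3781.55,7.65,3.47,200.79,119.97
overall,anti factor X activity increased,PT,10,61949,52373206,255.93,126.13,519.28,255.89,126.12,519.15,1948.46,7.62,2.41,196.61,96.90
overall,heparin-induced thrombocytopenia test,PT,14,61949,52373206,231.85,128.34,418.86,231.80,128.32,418.72,2524.35,7.51,2.97,182.09,100.79
overall,spontaneous heparin-induced thrombocytopenia syndrome,PT,3,61949,52373206,230.31,64.25,825.57,230.30,64.25,825.49,538.14,7.50,0.35,181.16,50.54
overall,heparin-induced thrombocytopenia,PT,510,61949,52373206,112.78,102.79,123.73,111.86,102.02,122.64,49482.42,6.63,6.24,98.89,90.14
overall,extradural haematoma,PT,62,61949,52373206,45.61,35.32,58.90,45.57,35.29,58.83,2564.10,5.44,4.32,43.28,33.52
overall,abdominal wall haematoma,PT,255,61949,52373206,145.99,127.79,166.78,145.39,127.33,166.02,31196.88,6.96,6.20,124.18,108.71
pregnancy,sternal fracture,PT,3,7840,1279728,243.44,40.67,1457.14,243.35,40.67,1456.18,289.62,6.61,0.09,97.94,16.36
pregnancy,syringe issue,PT,12,7840,1279728,97.49,47.64,199.49,97.34,47.60,199.05,715.13,5.94,2.49,61.21,29.91
pregnancy,bleeding time prolonged,PT,3,7840,1279728,97.38,23.27,407.53,97.34,23.27,407.24,178.78,5.94,0.19,61.21,14.63
pregnancy,spinal compression fracture,PT,10,7840,1279728,90.24,41.64,195.56,90.13,41.62,195.18,566.62,5.87,2.20,58.30,26.90
pregnancy,injection site haematoma,PT,19,7840,1279728,79.23,45.76,137.15,79.04,45.70,136.70,984.40,5.74,3.13,53.47,30.89
pregnancy,injection site bruising,PT,46,7840,1279728,19.70,14.49,26.77,19.59,14.44,26.58,724.18,4.14,3.25,17.58,12.94
pregnancy,thrombosis,PT,52,7840,1279728,14.19,10.68,18.86,14.11,10.64,18.71,582.89,3.71,3.00,13.06,9.83
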