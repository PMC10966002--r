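sex,age_group,cancer,n_counties,cum_cases,rate_mean,rate_sd
men,25-49,Colon and rectum,61,4444,16.7,6
men,25-49,Melanoma of the skin,58,2687,12.7,4.6
men,25-49,Kidney and renal pelvis,51,2915,11.1,4.2
men,25-49,Non-Hodgkin lymphoma,51,3288,9.9,3.3
men,25-49,Thyroid,47,3282,9.8,3.9
men,25-49,Prostate,48,3300,8.8,4.4
men,25-49,Lung and bronchus,49,1941,8.4,3.4
men,25-49,Leukemia,48,1951,7.9,5.6
men,50-69,Prostate,62,81193,350,62
men,50-69,Lung and bronchus,62,27331,155.2,30.2
men,50-69,Colon and rectum,62,18867,89.1,10.1
men,50-69,Kidney and renal pelvis,61,11739,56.3,11
men,50-69,Melanoma of the skin,62,8950,50.4,14.5
men,50-69,Non-Hodgkin lymphoma,61,10112,46.8,7.3
men,50-69,Leukemia,61,7425,37,7.7
men,50-69,Thyroid,55,4169,16.8,5.7
men,70-84,Prostate,62,41971,644.7,113.2
men,70-84,Lung and bronchus,62,26775,507.8,79.8
men,70-84,Colon and rectum,61,13846,230.1,44.3
men,70-84,Melanoma of the skin,61,7207,136.9,39.7
men,70-84,Non-Hodgkin lymphoma,61,7622,128.9,24.2
men,70-84,Leukemia,61,6561,116.3,27.9
men,70-84,Kidney and renal pelvis,61,6124,102.9,19.7
women,25-49,Breast,61,28204,89.5,14.3
women,25-49,Thyroid,61,12111,37.6,10.4
women,25-49,Melanoma of the skin,60,3607,19,7.6
women,25-49,Colon and rectum,57,4053,16.2,6.6
women,25-49,Corpus uteri,55,3470,14.5,6.8
women,25-49,Lung and bronchus,55,2385,11.6,5.2
women,25-49,Non-Hodgkin lymphoma,39,2411,7.1,3.3
women,25-49,Kidney and renal pelvis,42,1608,6.9,3.5
women,50-69,Breast,62,70389,303.8,26
women,50-69,Lung and bronchus,62,26582,142,30.5
women,50-69,Corpus uteri,62,21181,94.9,11.3
women,50-69,Colon and rectum,61,14945,64.7,11.4
women,50-69,Thyroid,61,10735,39.8,12.6
women,50-69,Non-Hodgkin lymphoma,61,8286,35.7,8.6
women,50-69,Melanoma of the skin,61,6255,34.3,9.8
women,50-69,Kidney and renal pelvis,61,5679,28,6.7
women,50-69,Leukemia,59,4937,22.6,6.6
women,70-84,Breast,62,36218,474.4,65.6
women,70-84,Lung and bronchus,62,27660,394.8,68.5
women,70-84,Colon and rectum,62,14032,189.7,39
women,70-84,Corpus uteri,61,9026,111,21
women,70-84,Non-Hodgkin lymphoma,60,7060,90.6,19.8
women,70-84,Leukemia,60,4563,60.4,15.7
women,70-84,Melanoma of the skin,60,3950,53.7,18.5
women,70-84,Kidney and renal pelvis,57,3771,51.9,15.1
women,70-84,Thyroid,40,2452,24.4,9.8
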