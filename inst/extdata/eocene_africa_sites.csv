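site,lat,lon,map_early_low,map_early_high,map_modern,uncertainty,method
"Koningsnaas, South Africa",-30.2,17.3,1318,1738,101,ci95,nlr
"Shagamu, Nigeria",6.7,3.7,1148,2089,1762,ci95,nlr
"Melut Basin, South Sudan",10,33,1175,1905,757,ci95,nlr
"Kwakwa, Cameroon",4.5,9.1,1175,1905,2524,ci95,nlr
"Mwadui, Tanzania",-3.9,33.5,813,1738,754,ci95,nlr
"Tano, Ghana",4.7,-3,1514,2344,NA,ci95,nlr
"Nanka, Nigeria",6.12,7,1380,2291,1683,ci95,nlr
"Abidjan margin, Cote d'Ivoire",5,-4.1,1660,1950,NA,ci95,nlr
"Okigwe, Nigeria",5.82,7.34,1175,1862,2311,ci95,nlr
"Bende - Umuahia, Nigeria",5.47,7.45,1514,2291,2311,ci95,nlr
"Araromi, Nigeria",7.7,3.5,1072,1738,1179,ci95,nlr
"Mahenge, Tanzania",-4.79,34.26,720,800,707,sd1,leaf_area
"Mahenge, Tanzania",-4.79,34.26,630,690,707,sd1,leaf_area
"Mahenge, Tanzania",-4.79,34.26,737,815,707,sd1,leaf_area
"Mahenge, Tanzania",-4.79,34.26,644,708,707,sd1,leaf_area
"Mahenge, Tanzania",-4.79,34.26,710,790,707,sd1,leaf_area
"Mahenge, Tanzania",-4.79,34.26,610,680,707,sd1,leaf_area
"Mahenge, Tanzania",-4.79,34.26,610,680,707,sd1,leaf_area
"Mahenge, Tanzania",-4.79,34.26,740,820,707,sd1,leaf_area
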