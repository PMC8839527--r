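station_id,chl_a_mg_m3,sum_c_mg_m3,spm_g_m3,spm_inorg_g_m3,a_cdom_400_m1,aph_420,ad_420,acdom_420,bbp_420,lu_420,ed_420,eu_420,rrs_420,aph_488,ad_488,acdom_488,bbp_488,lu_488,ed_488,eu_488,rrs_488,aph_555,ad_555,acdom_555,bbp_555,lu_555,ed_555,eu_555,rrs_555,aph_620,ad_620,acdom_620,bbp_620,lu_620,ed_620,eu_620,rrs_620
S0001,8.07617337367055,2.56303248940312,0.197451345654939,0.148776394115679,0.82862314374178,0.199576074173087,0.0345393237770651,0.387498829338247,0.00175314665502072,0.000386591920942567,1.02244731436672,0.00154636768377027,0.000378104490579069,0.232664969465852,0.0322352381613935,0.495401493062099,0.00206349574231984,0.000507509979728626,1.02244731436672,0.00203003991891451,0.000496367854458069,0.081078320619432,0.0233195970956699,0.113580350347767,0.00216258302965296,0.00111011360783479,1.02244731436672,0.00444045443133915,0.00108574162427368,0.0609855377171,0.0181537614760051,0.124296575614907,0.00256357985887327,0.000888028817075477,1.02244731436672,0.00355211526830191,0.000868532592924358
S0002,1.84966764326161,0.860112858619515,0.829449366803833,0.466218872645482,0.714353775298068,0.0685632488183439,0.05266513009893,0.442786333669935,0.0128018240788101,0.000925471561147824,1.06963983353447,0.0037018862445913,0.000865217928627191,0.0575297907971669,0.0336653594337619,0.328268172433489,0.00986126396975091,0.00415059504468633,1.06963983353447,0.0166023801787453,0.00388036693713182,0.0174187536582383,0.0479959645248376,0.0923550486055925,0.00577748369878499,0.00365881802623621,1.06963983353447,0.0146352721049449,0.00342060749004288,0.0121088456829368,0.0292564219360497,0.0795335187204423,0.00654258672952553,0.00191454686467107,1.06963983353447,0.00765818745868429,0.00178989862255292
S0003,5.68414633877849,1.89694593053819,0.659247462691875,0.300414971280043,0.903051836394927,0.170464043997889,0.0467885283322032,0.800979740144051,0.00737334930519867,0.000224335301012365,0.553030410468679,0.000897341204049459,0.000405647314805431,0.130967896146686,0.0422034304688273,0.281247423609675,0.00722151669260928,0.000538128818558299,0.553030410468679,0.0021525152742332,0.000973054660958424,0.0453624941795619,0.0695058742680068,0.22426819959981,0.00305867996552452,0.000819157802872548,0.553030410468679,0.00327663121149019,0.00148121656127071,0.0267575139974777,0.0309401984015417,0.0825245889873672,0.00262907629610783,0.00122964289787623,0.553030410468679,0.00491857159150492,0.00222346343817538
S0004,4.62456076574257,1.54982594825848,1.64374828801108,0.360151502929997,0.901232189495592,0.219699303636043,0.0602097174455744,0.990374215949771,0.0155850802264903,0.00211551063203574,1.54800975643118,0.00846204252814295,0.00136660032228278,0.0687074753208499,0.067269043126719,0.347813805498992,0.0121143433492879,0.00269498752099504,1.54800975643118,0.0107799500839802,0.00174093703854175,0.0489239862428173,0.0488265511480657,0.115046650897377,0.00840445035545678,0.00380994742852666,1.54800975643118,0.0152397897141066,0.00246119083726591,0.0201804003537345,0.0504694783711844,0.227465116642052,0.0132618155803246,0.00327416486339542,1.54800975643118,0.0130966594535817,0.00211508025049129
S0005,2.7059150504252,0.572601439958191,1.02391620264589,0.595846191561118,0.309473673985602,0.188325499020797,0.0705885505399949,0.204760068977415,0.022855675182298,0.00352248409027936,1.65433298955447,0.0140899363611175,0.00212924732355607,0.0870471760352947,0.0747047328587997,0.0803334815566921,0.00981406388509964,0.00688827346588874,1.65433298955447,0.027553093863555,0.00416377688735073,0.0258347734028552,0.0554591823525092,0.0204244582342565,0.0130789281333801,0.0170592091384842,1.65433298955447,0.0682368365539366,0.0103118351904947,0.0152816318828169,0.0355615247564348,0.0255242345502754,0.00648029431568206,0.00703164835905256,1.65433298955447,0.0281265934362103,0.00425044317162911
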