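"indicator","sex","key","L","M","S"
"waz","F",122,0.2,7.219,0.11
"waz","F",183,0.2,7.584,0.11
"waz","F",244,0.2,7.949,0.11
"waz","F",304,0.2,8.314,0.11
"waz","F",365,0.2,8.678,0.11
"waz","F",426,0.2,9.043,0.11
"waz","F",487,0.2,9.408,0.11
"waz","F",548,0.2,9.773,0.11
"waz","F",609,0.2,10.138,0.11
"waz","F",670,0.2,10.502,0.11
"waz","F",730,0.2,10.867,0.11
"waz","F",791,0.2,11.232,0.11
"waz","F",852,0.2,11.597,0.11
"waz","F",913,0.2,11.962,0.11
"waz","F",974,0.2,12.326,0.11
"waz","F",1035,0.2,12.691,0.11
"waz","F",1096,0.2,13.056,0.11
"waz","F",1157,0.2,13.421,0.11
"waz","F",1218,0.2,13.786,0.11
"waz","F",1278,0.2,14.15,0.11
"waz","F",1339,0.2,14.515,0.11
"waz","F",1400,0.2,14.88,0.11
"waz","F",1461,0.2,15.245,0.11
"waz","F",1522,0.2,15.61,0.11
"waz","F",1583,0.2,15.974,0.11
"waz","F",1644,0.2,16.339,0.11
"waz","F",1704,0.2,16.704,0.11
"waz","F",1765,0.2,17.069,0.11
"waz","F",1826,0.2,17.434,0.11
"waz","F",1887,0.2,17.798,0.11
"haz","F",122,1,62.78,0.035
"haz","F",183,1,64.32,0.035
"haz","F",244,1,65.86,0.035
"haz","F",304,1,67.39,0.035
"haz","F",365,1,68.93,0.035
"haz","F",426,1,70.46,0.035
"haz","F",487,1,72,0.035
"haz","F",548,1,73.54,0.035
"haz","F",609,1,75.07,0.035
"haz","F",670,1,76.61,0.035
"haz","F",730,1,78.14,0.035
"haz","F",791,1,79.68,0.035
"haz","F",852,1,81.22,0.035
"haz","F",913,1,82.75,0.035
"haz","F",974,1,84.29,0.035
"haz","F",1035,1,85.82,0.035
"haz","F",1096,1,87.36,0.035
"haz","F",1157,1,88.9,0.035
"haz","F",1218,1,90.43,0.035
"haz","F",1278,1,91.97,0.035
"haz","F",1339,1,93.5,0.035
"haz","F",1400,1,95.04,0.035
"haz","F",1461,1,96.58,0.035
"haz","F",1522,1,98.11,0.035
"haz","F",1583,1,99.65,0.035
"haz","F",1644,1,101.18,0.035
"haz","F",1704,1,102.72,0.035
"haz","F",1765,1,104.26,0.035
"haz","F",1826,1,105.79,0.035
"haz","F",1887,1,107.33,0.035
"whz","F",600,-0.35,5.971,0.082
"whz","F",610,-0.35,6.198,0.082
"whz","F",620,-0.35,6.424,0.082
"whz","F",630,-0.35,6.651,0.082
"whz","F",640,-0.35,6.877,0.082
"whz","F",650,-0.35,7.104,0.082
"whz","F",660,-0.35,7.331,0.082
"whz","F",670,-0.35,7.557,0.082
"whz","F",680,-0.35,7.784,0.082
"whz","F",690,-0.35,8.01,0.082
"whz","F",700,-0.35,8.237,0.082
"whz","F",710,-0.35,8.463,0.082
"whz","F",720,-0.35,8.69,0.082
"whz","F",730,-0.35,8.916,0.082
"whz","F",740,-0.35,9.143,0.082
"whz","F",750,-0.35,9.37,0.082
"whz","F",760,-0.35,9.596,0.082
"whz","F",770,-0.35,9.823,0.082
"whz","F",780,-0.35,10.049,0.082
"whz","F",790,-0.35,10.276,0.082
"whz","F",800,-0.35,10.502,0.082
"whz","F",810,-0.35,10.729,0.082
"whz","F",820,-0.35,10.956,0.082
"whz","F",830,-0.35,11.182,0.082
"whz","F",840,-0.35,11.409,0.082
"whz","F",850,-0.35,11.635,0.082
"whz","F",860,-0.35,11.862,0.082
"whz","F",870,-0.35,12.088,0.082
"whz","F",880,-0.35,12.315,0.082
"whz","F",890,-0.35,12.541,0.082
"whz","F",900,-0.35,12.768,0.082
"whz","F",910,-0.35,12.995,0.082
"whz","F",920,-0.35,13.221,0.082
"whz","F",930,-0.35,13.448,0.082
"whz","F",940,-0.35,13.674,0.082
"whz","F",950,-0.35,13.901,0.082
"whz","F",960,-0.35,14.127,0.082
"whz","F",970,-0.35,14.354,0.082
"whz","F",980,-0.35,14.58,0.082
"whz","F",990,-0.35,14.807,0.082
"whz","F",1000,-0.35,15.034,0.082
"whz","F",1010,-0.35,15.26,0.082
"whz","F",1020,-0.35,15.487,0.082
"whz","F",1030,-0.35,15.713,0.082
"whz","F",1040,-0.35,15.94,0.082
"whz","F",1050,-0.35,16.166,0.082
"whz","F",1060,-0.35,16.393,0.082
"whz","F",1070,-0.35,16.62,0.082
"whz","F",1080,-0.35,16.846,0.082
"whz","F",1090,-0.35,17.073,0.082
"whz","F",1100,-0.35,17.299,0.082
"whz","F",1110,-0.35,17.526,0.082
"whz","F",1120,-0.35,17.752,0.082
"whz","F",1130,-0.35,17.979,0.082
"whz","F",1140,-0.35,18.205,0.082
"whz","F",1150,-0.35,18.432,0.082
"whz","F",1160,-0.35,18.659,0.082
"whz","F",1170,-0.35,18.885,0.082
"whz","F",1180,-0.35,19.112,0.082
"whz","F",1190,-0.35,19.338,0.082
"whz","F",1200,-0.35,19.565,0.082
"whz","F",1210,-0.35,19.791,0.082
"whz","F",1220,-0.35,20.018,0.082
"whz","F",1230,-0.35,20.244,0.082
"whz","F",1240,-0.35,20.471,0.082
"whz","F",1250,-0.35,20.698,0.082
"waz","M",122,0.2,7.52,0.11
"waz","M",183,0.2,7.9,0.11
"waz","M",244,0.2,8.28,0.11
"waz","M",304,0.2,8.66,0.11
"waz","M",365,0.2,9.04,0.11
"waz","M",426,0.2,9.42,0.11
"waz","M",487,0.2,9.8,0.11
"waz","M",548,0.2,10.18,0.11
"waz","M",609,0.2,10.56,0.11
"waz","M",670,0.2,10.94,0.11
"waz","M",730,0.2,11.32,0.11
"waz","M",791,0.2,11.7,0.11
"waz","M",852,0.2,12.08,0.11
"waz","M",913,0.2,12.46,0.11
"waz","M",974,0.2,12.84,0.11
"waz","M",1035,0.2,13.22,0.11
"waz","M",1096,0.2,13.6,0.11
"waz","M",1157,0.2,13.98,0.11
"waz","M",1218,0.2,14.36,0.11
"waz","M",1278,0.2,14.74,0.11
"waz","M",1339,0.2,15.12,0.11
"waz","M",1400,0.2,15.5,0.11
"waz","M",1461,0.2,15.88,0.11
"waz","M",1522,0.2,16.26,0.11
"waz","M",1583,0.2,16.64,0.11
"waz","M",1644,0.2,17.02,0.11
"waz","M",1704,0.2,17.4,0.11
"waz","M",1765,0.2,17.78,0.11
"waz","M",1826,0.2,18.16,0.11
"waz","M",1887,0.2,18.54,0.11
"haz","M",122,1,65.4,0.035
"haz","M",183,1,67,0.035
"haz","M",244,1,68.6,0.035
"haz","M",304,1,70.2,0.035
"haz","M",365,1,71.8,0.035
"haz","M",426,1,73.4,0.035
"haz","M",487,1,75,0.035
"haz","M",548,1,76.6,0.035
"haz","M",609,1,78.2,0.035
"haz","M",670,1,79.8,0.035
"haz","M",730,1,81.4,0.035
"haz","M",791,1,83,0.035
"haz","M",852,1,84.6,0.035
"haz","M",913,1,86.2,0.035
"haz","M",974,1,87.8,0.035
"haz","M",1035,1,89.4,0.035
"haz","M",1096,1,91,0.035
"haz","M",1157,1,92.6,0.035
"haz","M",1218,1,94.2,0.035
"haz","M",1278,1,95.8,0.035
"haz","M",1339,1,97.4,0.035
"haz","M",1400,1,99,0.035
"haz","M",1461,1,100.6,0.035
"haz","M",1522,1,102.2,0.035
"haz","M",1583,1,103.8,0.035
"haz","M",1644,1,105.4,0.035
"haz","M",1704,1,107,0.035
"haz","M",1765,1,108.6,0.035
"haz","M",1826,1,110.2,0.035
"haz","M",1887,1,111.8,0.035
"whz","M",600,-0.35,6.22,0.082
"whz","M",610,-0.35,6.456,0.082
"whz","M",620,-0.35,6.692,0.082
"whz","M",630,-0.35,6.928,0.082
"whz","M",640,-0.35,7.164,0.082
"whz","M",650,-0.35,7.4,0.082
"whz","M",660,-0.35,7.636,0.082
"whz","M",670,-0.35,7.872,0.082
"whz","M",680,-0.35,8.108,0.082
"whz","M",690,-0.35,8.344,0.082
"whz","M",700,-0.35,8.58,0.082
"whz","M",710,-0.35,8.816,0.082
"whz","M",720,-0.35,9.052,0.082
"whz","M",730,-0.35,9.288,0.082
"whz","M",740,-0.35,9.524,0.082
"whz","M",750,-0.35,9.76,0.082
"whz","M",760,-0.35,9.996,0.082
"whz","M",770,-0.35,10.232,0.082
"whz","M",780,-0.35,10.468,0.082
"whz","M",790,-0.35,10.704,0.082
"whz","M",800,-0.35,10.94,0.082
"whz","M",810,-0.35,11.176,0.082
"whz","M",820,-0.35,11.412,0.082
"whz","M",830,-0.35,11.648,0.082
"whz","M",840,-0.35,11.884,0.082
"whz","M",850,-0.35,12.12,0.082
"whz","M",860,-0.35,12.356,0.082
"whz","M",870,-0.35,12.592,0.082
"whz","M",880,-0.35,12.828,0.082
"whz","M",890,-0.35,13.064,0.082
"whz","M",900,-0.35,13.3,0.082
"whz","M",910,-0.35,13.536,0.082
"whz","M",920,-0.35,13.772,0.082
"whz","M",930,-0.35,14.008,0.082
"whz","M",940,-0.35,14.244,0.082
"whz","M",950,-0.35,14.48,0.082
"whz","M",960,-0.35,14.716,0.082
"whz","M",970,-0.35,14.952,0.082
"whz","M",980,-0.35,15.188,0.082
"whz","M",990,-0.35,15.424,0.082
"whz","M",1000,-0.35,15.66,0.082
"whz","M",1010,-0.35,15.896,0.082
"whz","M",1020,-0.35,16.132,0.082
"whz","M",1030,-0.35,16.368,0.082
"whz","M",1040,-0.35,16.604,0.082
"whz","M",1050,-0.35,16.84,0.082
"whz","M",1060,-0.35,17.076,0.082
"whz","M",1070,-0.35,17.312,0.082
"whz","M",1080,-0.35,17.548,0.082
"whz","M",1090,-0.35,17.784,0.082
"whz","M",1100,-0.35,18.02,0.082
"whz","M",1110,-0.35,18.256,0.082
"whz","M",1120,-0.35,18.492,0.082
"whz","M",1130,-0.35,18.728,0.082
"whz","M",1140,-0.35,18.964,0.082
"whz","M",1150,-0.35,19.2,0.082
"whz","M",1160,-0.35,19.436,0.082
"whz","M",1170,-0.35,19.672,0.082
"whz","M",1180,-0.35,19.908,0.082
"whz","M",1190,-0.35,20.144,0.082
"whz","M",1200,-0.35,20.38,0.082
"whz","M",1210,-0.35,20.616,0.082
"whz","M",1220,-0.35,20.852,0.082
"whz","M",1230,-0.35,21.088,0.082
"whz","M",1240,-0.35,21.324,0.082
"whz","M",1250,-0.35,21.56,0.082
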