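antigen,control,ls_mfi,lc_mfi
NC,negative_control,0,0
PC,positive_control,12,0
A*01:01,none,933,0
A*02:01,none,339,0
A*02:02,none,NA,0
A*02:03,none,1018,0
A*02:05,none,NA,0
A*02:06,none,1230,NA
A*03:01,none,193,0
A*11:01,none,4782,0
A*11:02,none,537,0
A*23:01,none,133,0
A*24:02,none,716,0
A*24:03,none,2516,0
A*25:01,none,194,0
A*26:01,none,2221,0
A*29:01,none,1017,0
A*29:02,none,778,0
A*30:01,none,1496,0
A*30:02,none,1135,NA
A*31:01,none,396,0
A*32:01,none,515,0
A*33:01,none,1038,0
A*33:03,none,554,0
A*34:01,none,2616,NA
A*34:02,none,1535,0
A*36:01,none,1353,0
A*43:01,none,2479,0
A*66:01,none,1886,0
A*66:02,none,1454,0
A*68:01,none,713,0
A*68:02,none,1185,0
A*69:01,none,3128,0
A*74:01,none,652,0
A*80:01,none,3132,0
B*07:02,none,862,0
B*07:03,none,NA,0
B*08:01,none,1226,0
B*13:01,none,6915,NA
B*13:02,none,2514,12
B*14:01,none,7805,0
B*14:02,none,1831,3
B*15:01,none,335,0
B*15:02,none,1935,0
B*15:03,none,1822,0
B*15:10,none,1010,NA
B*15:11,none,5165,NA
B*15:12,none,770,0
B*15:13,none,3135,0
B*15:16,none,3076,0
B*15:18,none,NA,0
B*18:01,none,3096,0
B*27:03,none,NA,0
B*27:05,none,634,0
B*27:08,none,1659,0
B*35:01,none,6128,0
B*35:08,none,NA,0
B*37:01,none,2650,0
B*38:01,none,2521,0
B*39:01,none,704,0
B*40:01,none,3429,0
B*40:02,none,2697,0
B*40:06,none,10684,NA
B*41:01,none,3739,0
B*42:01,none,347,0
B*44:02,none,3650,0
B*44:03,none,1829,0
B*45:01,none,1736,0
B*46:01,none,3572,0
B*47:01,none,2152,0
B*48:01,none,3262,10
B*49:01,none,1554,0
B*50:01,none,1799,0
B*51:01,none,2461,8
B*51:02,none,2695,NA
B*52:01,none,2146,0
B*53:01,none,5442,2
B*54:01,none,1662,0
B*55:01,none,2519,0
B*56:01,none,3662,0
B*57:01,none,2089,0
B*57:03,none,2260,NA
B*58:01,none,5268,0
B*59:01,none,3553,1
B*67:01,none,406,0
B*73:01,none,1423,2
B*78:01,none,2996,0
B*81:01,none,1525,0
B*82:01,none,3442,NA
B*82:02,none,NA,0
Cw*01:02,none,4066,1
Cw*02:02,none,7446,20
Cw*03:02,none,2889,NA
Cw*03:03,none,2458,0
Cw*03:04,none,4504,0
Cw*04:01,none,3337,8
Cw*04:03,none,NA,0
Cw*05:01,none,9124,24
Cw*06:02,none,5644,4
Cw*07:01,none,NA,27
Cw*07:02,none,870,297
Cw*08:01,none,6090,1
Cw*08:02,none,NA,3
Cw*12:02,none,NA,10
Cw*12:03,none,3562,NA
Cw*14:02,none,3937,0
Cw*15:02,none,4465,4
Cw*16:01,none,4648,0
Cw*17:01,none,8296,10
Cw*18:01,none,NA,0
Cw*18:02,none,8015,NA
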