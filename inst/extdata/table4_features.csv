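year,pair,feature,value
2000,NPP_FP,fp_threshold,6.13
2001,NPP_FP,fp_threshold,5.64
2002,NPP_FP,fp_threshold,5.54
2003,NPP_FP,fp_threshold,5.64
2004,NPP_FP,fp_threshold,5.96
2005,NPP_FP,fp_threshold,6.06
2006,NPP_FP,fp_threshold,6.53
2007,NPP_FP,fp_threshold,6.59
2008,NPP_FP,fp_threshold,7.29
2009,NPP_FP,fp_threshold,7.11
2010,NPP_FP,fp_threshold,7.15
2011,NPP_FP,fp_threshold,7.61
2012,NPP_FP,fp_threshold,7.19
2013,NPP_FP,fp_threshold,8.09
2014,NPP_FP,fp_threshold,7.74
2015,NPP_FP,fp_threshold,8.25
2016,NPP_FP,fp_threshold,8.21
2017,NPP_FP,fp_threshold,8.72
2018,NPP_FP,fp_threshold,9.27
2019,NPP_FP,fp_threshold,9.3
2020,NPP_FP,fp_threshold,9.03
2000,NPP_FP,npp_threshold,6
2001,NPP_FP,npp_threshold,5.4
2002,NPP_FP,npp_threshold,6.5
2003,NPP_FP,npp_threshold,9.5
2004,NPP_FP,npp_threshold,5.4
2005,NPP_FP,npp_threshold,8.6
2006,NPP_FP,npp_threshold,4.7
2007,NPP_FP,npp_threshold,6.4
2008,NPP_FP,npp_threshold,5.4
2009,NPP_FP,npp_threshold,6.3
2010,NPP_FP,npp_threshold,5.5
2011,NPP_FP,npp_threshold,5.3
2012,NPP_FP,npp_threshold,5.5
2013,NPP_FP,npp_threshold,5.6
2014,NPP_FP,npp_threshold,6.6
2015,NPP_FP,npp_threshold,7.6
2016,NPP_FP,npp_threshold,6.2
2017,NPP_FP,npp_threshold,5.4
2018,NPP_FP,npp_threshold,5.4
2019,NPP_FP,npp_threshold,5
2020,NPP_FP,npp_threshold,4.9
2000,NPP_SC,npp_threshold,3.75
2001,NPP_SC,npp_threshold,4.68
2002,NPP_SC,npp_threshold,4.29
2003,NPP_SC,npp_threshold,5.19
2004,NPP_SC,npp_threshold,7.45
2005,NPP_SC,npp_threshold,4.88
2006,NPP_SC,npp_threshold,4.69
2007,NPP_SC,npp_threshold,4.53
2008,NPP_SC,npp_threshold,4.31
2009,NPP_SC,npp_threshold,5.25
2010,NPP_SC,npp_threshold,3.99
2011,NPP_SC,npp_threshold,3.61
2012,NPP_SC,npp_threshold,5.15
2013,NPP_SC,npp_threshold,5.61
2014,NPP_SC,npp_threshold,3.95
2015,NPP_SC,npp_threshold,4.98
2016,NPP_SC,npp_threshold,3.54
2017,NPP_SC,npp_threshold,4.84
2018,NPP_SC,npp_threshold,4.66
2019,NPP_SC,npp_threshold,4.97
2020,NPP_SC,npp_threshold,5.06
2000,NPP_SC,sc_threshold,1386.35
2001,NPP_SC,sc_threshold,1517.8
2002,NPP_SC,sc_threshold,332.45
2003,NPP_SC,sc_threshold,1306.24
2004,NPP_SC,sc_threshold,3254.79
2005,NPP_SC,sc_threshold,1139.83
2006,NPP_SC,sc_threshold,725.93
2007,NPP_SC,sc_threshold,1212.9
2008,NPP_SC,sc_threshold,1510.45
2009,NPP_SC,sc_threshold,945.13
2010,NPP_SC,sc_threshold,1627.28
2011,NPP_SC,sc_threshold,1033.68
2012,NPP_SC,sc_threshold,1975.39
2013,NPP_SC,sc_threshold,1996.45
2014,NPP_SC,sc_threshold,504.21
2015,NPP_SC,sc_threshold,559.82
2016,NPP_SC,sc_threshold,1202.79
2017,NPP_SC,sc_threshold,893.33
2018,NPP_SC,sc_threshold,1165.07
2019,NPP_SC,sc_threshold,1795.86
2020,NPP_SC,sc_threshold,1545.14
2000,NPP_WY,npp_threshold,3.54
2001,NPP_WY,npp_threshold,4.12
2002,NPP_WY,npp_threshold,3.96
2003,NPP_WY,npp_threshold,3.49
2004,NPP_WY,npp_threshold,2.88
2005,NPP_WY,npp_threshold,4.04
2006,NPP_WY,npp_threshold,4.06
2007,NPP_WY,npp_threshold,4
2008,NPP_WY,npp_threshold,4.56
2009,NPP_WY,npp_threshold,4.61
2010,NPP_WY,npp_threshold,4.77
2011,NPP_WY,npp_threshold,4.75
2012,NPP_WY,npp_threshold,4.68
2013,NPP_WY,npp_threshold,4.88
2014,NPP_WY,npp_threshold,4.57
2015,NPP_WY,npp_threshold,4.69
2016,NPP_WY,npp_threshold,4.76
2017,NPP_WY,npp_threshold,5.73
2018,NPP_WY,npp_threshold,6.08
2019,NPP_WY,npp_threshold,5.98
2020,NPP_WY,npp_threshold,6.07
2000,NPP_WY,wy_threshold,1379.62
2001,NPP_WY,wy_threshold,803
2002,NPP_WY,wy_threshold,978.35
2003,NPP_WY,wy_threshold,1439.64
2004,NPP_WY,wy_threshold,1100.41
2005,NPP_WY,wy_threshold,1146.43
2006,NPP_WY,wy_threshold,954.79
2007,NPP_WY,wy_threshold,1218.52
2008,NPP_WY,wy_threshold,962.81
2009,NPP_WY,wy_threshold,772.81
2010,NPP_WY,wy_threshold,781.59
2011,NPP_WY,wy_threshold,927.59
2012,NPP_WY,wy_threshold,916.55
2013,NPP_WY,wy_threshold,696.88
2014,NPP_WY,wy_threshold,1025.3
2015,NPP_WY,wy_threshold,1006.75
2016,NPP_WY,wy_threshold,1042.39
2017,NPP_WY,wy_threshold,1042.21
2018,NPP_WY,wy_threshold,1200.92
2019,NPP_WY,wy_threshold,693.92
2020,NPP_WY,wy_threshold,1194.82
2000,SC_FP,b,6.53
2001,SC_FP,b,5.6
2002,SC_FP,b,6.02
2003,SC_FP,b,5.62
2004,SC_FP,b,5.64
2005,SC_FP,b,6.34
2006,SC_FP,b,6.8
2007,SC_FP,b,6.95
2008,SC_FP,b,7.18
2009,SC_FP,b,7.28
2010,SC_FP,b,7.09
2011,SC_FP,b,7.39
2012,SC_FP,b,7.11
2013,SC_FP,b,8.24
2014,SC_FP,b,8.17
2015,SC_FP,b,8.28
2016,SC_FP,b,8.61
2017,SC_FP,b,8.82
2018,SC_FP,b,9.91
2019,SC_FP,b,8.72
2020,SC_FP,b,9.01
2000,SC_FP,k,0.9995
2001,SC_FP,k,0.9997
2002,SC_FP,k,0.9991
2003,SC_FP,k,0.9997
2004,SC_FP,k,0.9998
2005,SC_FP,k,0.9997
2006,SC_FP,k,0.9995
2007,SC_FP,k,0.9997
2008,SC_FP,k,0.9997
2009,SC_FP,k,0.9996
2010,SC_FP,k,0.9997
2011,SC_FP,k,0.9996
2012,SC_FP,k,0.9998
2013,SC_FP,k,0.9998
2014,SC_FP,k,0.9993
2015,SC_FP,k,0.9993
2016,SC_FP,k,0.9995
2017,SC_FP,k,0.9996
2018,SC_FP,k,0.9995
2019,SC_FP,k,0.9998
2020,SC_FP,k,0.9998
2000,WY_FP,fp_threshold,5.91
2001,WY_FP,fp_threshold,5.72
2002,WY_FP,fp_threshold,5.5
2003,WY_FP,fp_threshold,5.25
2004,WY_FP,fp_threshold,5.91
2005,WY_FP,fp_threshold,6.02
2006,WY_FP,fp_threshold,6.72
2007,WY_FP,fp_threshold,6.93
2008,WY_FP,fp_threshold,7.37
2009,WY_FP,fp_threshold,7.14
2010,WY_FP,fp_threshold,7.27
2011,WY_FP,fp_threshold,7.73
2012,WY_FP,fp_threshold,7.33
2013,WY_FP,fp_threshold,8.29
2014,WY_FP,fp_threshold,7.81
2015,WY_FP,fp_threshold,8.24
2016,WY_FP,fp_threshold,8.25
2017,WY_FP,fp_threshold,8.86
2018,WY_FP,fp_threshold,9.49
2019,WY_FP,fp_threshold,9.38
2020,WY_FP,fp_threshold,9.16
2000,WY_FP,wy_threshold,587.2
2001,WY_FP,wy_threshold,367.3
2002,WY_FP,wy_threshold,424.2
2003,WY_FP,wy_threshold,884.7
2004,WY_FP,wy_threshold,402.5
2005,WY_FP,wy_threshold,684.8
2006,WY_FP,wy_threshold,486.4
2007,WY_FP,wy_threshold,555.8
2008,WY_FP,wy_threshold,614.1
2009,WY_FP,wy_threshold,470.1
2010,WY_FP,wy_threshold,453.3
2011,WY_FP,wy_threshold,505.5
2012,WY_FP,wy_threshold,517.5
2013,WY_FP,wy_threshold,270.8
2014,WY_FP,wy_threshold,517.1
2015,WY_FP,wy_threshold,468.9
2016,WY_FP,wy_threshold,587
2017,WY_FP,wy_threshold,525.7
2018,WY_FP,wy_threshold,544.7
2019,WY_FP,wy_threshold,286.7
2020,WY_FP,wy_threshold,594.8
2000,WY_SC,sc_threshold,1183.14
2001,WY_SC,sc_threshold,1611.79
2002,WY_SC,sc_threshold,338.98
2003,WY_SC,sc_threshold,1296.03
2004,WY_SC,sc_threshold,4006.01
2005,WY_SC,sc_threshold,1197.49
2006,WY_SC,sc_threshold,695.95
2007,WY_SC,sc_threshold,1301.24
2008,WY_SC,sc_threshold,1669.39
2009,WY_SC,sc_threshold,884.83
2010,WY_SC,sc_threshold,1572.66
2011,WY_SC,sc_threshold,1066.09
2012,WY_SC,sc_threshold,2183.67
2013,WY_SC,sc_threshold,2257.91
2014,WY_SC,sc_threshold,478.84
2015,WY_SC,sc_threshold,527.14
2016,WY_SC,sc_threshold,1173.02
2017,WY_SC,sc_threshold,924.2
2018,WY_SC,sc_threshold,1039.53
2019,WY_SC,sc_threshold,1989.14
2020,WY_SC,sc_threshold,1742.78
2000,WY_SC,wy_threshold,554.12
2001,WY_SC,wy_threshold,460.27
2002,WY_SC,wy_threshold,300.01
2003,WY_SC,wy_threshold,1021.36
2004,WY_SC,wy_threshold,1038.03
2005,WY_SC,wy_threshold,761.87
2006,WY_SC,wy_threshold,321.33
2007,WY_SC,wy_threshold,784.28
2008,WY_SC,wy_threshold,652.23
2009,WY_SC,wy_threshold,418.19
2010,WY_SC,wy_threshold,468.34
2011,WY_SC,wy_threshold,582.29
2012,WY_SC,wy_threshold,599.66
2013,WY_SC,wy_threshold,473.73
2014,WY_SC,wy_threshold,301.9
2015,WY_SC,wy_threshold,373.17
2016,WY_SC,wy_threshold,183.32
2017,WY_SC,wy_threshold,259.75
2018,WY_SC,wy_threshold,191.2
2019,WY_SC,wy_threshold,420.26
2020,WY_SC,wy_threshold,760.21
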