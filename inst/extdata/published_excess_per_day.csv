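period_id,day,excess
2007_oct20_24,1,-6
2007_oct20_24,2,1
2007_oct20_24,3,28
2007_oct20_24,4,13
2007_oct20_24,5,19
2007_oct22_26,1,28
2007_oct22_26,2,13
2007_oct22_26,3,19
2007_oct22_26,4,27
2007_oct22_26,5,10
2007_oct24_28,1,19
2007_oct24_28,2,27
2007_oct24_28,3,10
2007_oct24_28,4,7
2007_oct24_28,5,-5
2003_oct22_26,1,7
2003_oct22_26,2,-10
2003_oct22_26,3,-16
2003_oct22_26,4,-2
2003_oct22_26,5,6
2003_oct24_28,1,-16
2003_oct24_28,2,-2
2003_oct24_28,3,6
2003_oct24_28,4,12
2003_oct24_28,5,-1
2003_oct26_30,1,6
2003_oct26_30,2,12
2003_oct26_30,3,-1
2003_oct26_30,4,5
2003_oct26_30,5,8
2000_oct22_26,1,-2
2000_oct22_26,2,-8
2000_oct22_26,3,0
2000_oct22_26,4,10
2000_oct22_26,5,22
2000_oct26_30,1,22
2000_oct26_30,2,2
2000_oct26_30,3,-4
2000_oct26_30,4,6
2000_oct26_30,5,-4
2004_oct22_26,1,0
2004_oct22_26,2,3
2004_oct22_26,3,3
2004_oct22_26,4,5
2004_oct22_26,5,-1
2004_oct26_30,1,-1
2004_oct26_30,2,4
2004_oct26_30,3,-1
2004_oct26_30,4,-10
2004_oct26_30,5,-8
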