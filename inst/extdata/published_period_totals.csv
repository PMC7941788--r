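period_id,year,window,printed_total_excess,total_count,wildfire,main
2007_oct20_24,2007,Oct 20-24,54,273,TRUE,FALSE
2007_oct22_26,2007,Oct 22-26,96,325,TRUE,TRUE
2007_oct24_28,2007,Oct 24-28,58,267,TRUE,FALSE
2003_oct22_26,2003,Oct 22-26,-14,199,TRUE,FALSE
2003_oct24_28,2003,Oct 24-28,-1,221,TRUE,FALSE
2003_oct26_30,2003,Oct 26-30,30,257,TRUE,TRUE
2000_oct22_26,2000,Oct 22-26,23,274,FALSE,TRUE
2000_oct26_30,2000,Oct 26-30,23,261,FALSE,FALSE
2004_oct22_26,2004,Oct 22-26,10,198,FALSE,TRUE
2004_oct26_30,2004,Oct 26-30,-15,187,FALSE,FALSE
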