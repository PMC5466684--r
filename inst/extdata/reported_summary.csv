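statistic,value
n_records,1000
min_per_1e5,0.00
max_per_1e5,111.72
mean_per_1e5,42.06
sd_per_1e5,28.55
cases_2008,1643
cases_2009,1727
cases_2010,1820
cases_2011,1812
cases_2012,1782
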