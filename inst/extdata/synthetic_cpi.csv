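year,index
2009,94.5
2010,97.6
2011,101.3
2012,104.4
2013,106.7
2014,108.7
2015,107.7
2016,107.9
2017,108.6
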