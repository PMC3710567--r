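year,cpi
1999,166.6
2000,172.2
2001,177.1
2002,179.9
2003,184.0
2004,188.9
2005,195.3
2006,201.6
2007,207.3
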