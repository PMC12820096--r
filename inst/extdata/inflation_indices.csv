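index_type,year,value
NHSCII,2014,100.0
NHSCII,2015,101.2
NHSCII,2016,102.1
NHSCII,2017,103.8
NHSCII,2018,105.2
NHSCII,2019,107.9
NHSCII,2020,110.1
NHSCII,2021,111.5
NHSCII,2022,118.4
NHSCII,2023,125.1
NHSCII,2024,128.0
CPI,2014,100.0
CPI,2015,100.0
CPI,2016,100.7
CPI,2017,103.4
CPI,2018,105.9
CPI,2019,107.8
CPI,2020,108.7
CPI,2021,111.5
CPI,2022,121.6
CPI,2023,129.7
CPI,2024,133.0
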