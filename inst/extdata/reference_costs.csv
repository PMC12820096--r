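category,perspective,annual_mean,annual_median,annual_se,lessfreq_mean,lessfreq_median,lessfreq_se,printed_mean_difference
community,healthcare,960,560,1431,1002,682,1206,41
prescribed,healthcare,43,0,205,37,0,182,-6
admitted,healthcare,3579,541,8058,3553,496,8486,-26
outpatient,healthcare,2864,2021,2976,2631,1839,2990,-234
mammogram,healthcare,524,576,121,206,231,100,-319
total_healthcare,healthcare,7971,4434,10250,7428,3991,10590,-543
nonprescribed,societal,23,0,113,20,0,92,-3
private,societal,372,0,2237,232,0,1507,-139
other_expenses,societal,214,0,1402,172,0,1435,-42
travel,societal,219,109,370,188,106,269,-31
parking,societal,47,15,133,44,15,131,-3
timeoff,societal,634,0,2641,499,0,2465,-135
incapacity,societal,570,0,2819,484,0,2651,-86
informal_care,societal,2347,0,7608,1848,0,6031,-499
timeoff_family,societal,150,0,1507,87,0,840,-63
total_societal,societal,12546,6867,15864,11003,5745,14674,-1543
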