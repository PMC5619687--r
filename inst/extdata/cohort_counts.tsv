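study	population	n_cases_overall	n_cases_er_negative	n_controls
AABC	African American	3016	988	2745
BPC3	European American	NA	1998	3263
CGEMS	European American	1142	NA	1145
ROOT	African	1657	403	2029
SBCGS	Asian	2790	490	2176
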