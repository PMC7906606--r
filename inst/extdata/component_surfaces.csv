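component,time_h,surface_um2,surface_sd
MGDG,0,1.11E+07,0.03E+07
MGDG,4,1.15E+07,0.1E+07
MGDG,8,1.11E+07,0.1E+07
MGDG,12,1.75E+07,0.18E+07
MGDG,24,4.16E+07,0.4E+07
MGDG,48,8.65E+07,0.6E+07
MGDG,72,1.68E+08,0.09E+08
MGDG,96,2.35E+08,0.2E+07
DGDG,0,3.64E+06,0.4E+06
DGDG,4,4.23E+06,0.5E+06
DGDG,8,4.10E+06,0.1E+06
DGDG,12,6.26E+06,0.5E+05
DGDG,24,1.32E+07,0.1E+07
DGDG,48,2.32E+07,0.2E+07
DGDG,72,3.97E+07,0.3E+07
DGDG,96,5.48E+07,0.41E+07
PSII-LHCII,0,2.04E+06,0.5E+05
PSII-LHCII,4,2.74E+06,0.5E+05
PSII-LHCII,8,4.40E+06,0.2E+06
PSII-LHCII,12,9.91E+06,1.3E+06
PSII-LHCII,24,2.75E+07,0.6E+07
PSII-LHCII,48,6.06E+07,0.2E+07
PSII-LHCII,72,1.15E+08,0.2E+08
PSII-LHCII,96,1.83E+08,0.5E+08
PSI,0,0E+00,0E+00
PSI,4,0E+00,0E+00
PSI,8,0E+00,0E+00
PSI,12,8.95E+05,4.49E+05
PSI,24,1.33E+07,0.4E+07
PSI,48,2.10E+07,1.30E+07
PSI,72,3.04E+07,0.8E+07
PSI,96,4.24E+07,1.89E+07
Cyt b6f,0,7.99E+05,2.33E+05
Cyt b6f,4,8.43E+05,2.91E+05
Cyt b6f,8,7.5E+05,1.33E+05
Cyt b6f,12,1.57E+06,0.7E+06
Cyt b6f,24,3.44E+06,1.22E+06
Cyt b6f,48,5.30E+06,1.01E+06
Cyt b6f,72,1.69E+07,0.5E+06
Cyt b6f,96,2.37E+07,1.11E+07
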