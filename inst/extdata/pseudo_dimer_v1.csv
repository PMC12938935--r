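"x","y","z","dx","dy","dz","epsilon_cm1","trp","tubulin","spiral","filament"
7,0,0,0,0.819152044288992,0.573576436351046,0,1,0,0,0
-1.21553724366851,6.89365427108546,5.5,-0.806707284111599,-0.142244259722924,0.573576436351046,0,2,0,0,0
-6.57784834550136,-2.39414100327968,11,0.280166499593235,-0.769751131320057,0.573576436351046,0,3,0,0,0
3.5,-6.06217782649107,16.5,0.709406479916223,0.409576022144496,0.573576436351046,0,4,0,0,0
5.36231110183285,4.49951326780577,22,-0.526540784518363,0.627506871597133,0.573576436351046,0,5,0,0,0
-5.36231110183284,4.49951326780578,27.5,-0.526540784518364,-0.627506871597132,0.573576436351046,0,6,0,0,0
-3.5,-6.06217782649107,33,0.709406479916223,-0.409576022144496,0.573576436351046,0,7,0,0,0
6.57784834550135,-2.39414100327969,38.5,0.280166499593237,0.769751131320057,0.573576436351046,0,8,0,0,0
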