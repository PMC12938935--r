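{"format":"trp_network","version":1,"lambda0":280,"gamma":1,"gamma_unit":"gamma","sites":[{"x":7,"y":0,"z":0,"dx":-0,"dy":0.819152044288992,"dz":0.573576436351046,"epsilon_cm1":0,"trp":1,"tubulin":0,"spiral":0,"filament":0},{"x":-1.21553724366851,"y":6.89365427108546,"z":5.5,"dx":-0.806707284111599,"dy":-0.142244259722924,"dz":0.573576436351046,"epsilon_cm1":0,"trp":2,"tubulin":0,"spiral":0,"filament":0},{"x":-6.57784834550136,"y":-2.39414100327968,"z":11,"dx":0.280166499593235,"dy":-0.769751131320057,"dz":0.573576436351046,"epsilon_cm1":0,"trp":3,"tubulin":0,"spiral":0,"filament":0},{"x":3.5,"y":-6.06217782649107,"z":16.5,"dx":0.709406479916223,"dy":0.409576022144496,"dz":0.573576436351046,"epsilon_cm1":0,"trp":4,"tubulin":0,"spiral":0,"filament":0},{"x":5.36231110183285,"y":4.49951326780577,"z":22,"dx":-0.526540784518363,"dy":0.627506871597133,"dz":0.573576436351046,"epsilon_cm1":0,"trp":5,"tubulin":0,"spiral":0,"filament":0},{"x":-5.36231110183284,"y":4.49951326780578,"z":27.5,"dx":-0.526540784518364,"dy":-0.627506871597132,"dz":0.573576436351046,"epsilon_cm1":0,"trp":6,"tubulin":0,"spiral":0,"filament":0},{"x":-3.5,"y":-6.06217782649107,"z":33,"dx":0.709406479916223,"dy":-0.409576022144496,"dz":0.573576436351046,"epsilon_cm1":0,"trp":7,"tubulin":0,"spiral":0,"filament":0},{"x":6.57784834550135,"y":-2.39414100327969,"z":38.5,"dx":0.280166499593237,"dy":0.769751131320057,"dz":0.573576436351046,"epsilon_cm1":0,"trp":8,"tubulin":0,"spiral":0,"filament":0}],"provenance":{"template":"synthetic","description":"helical 8-site synthetic dimer template","fixture":"pseudo_dimer","n_sites":8,"spacing":15,"orientation":"parallel","seed":1}}
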