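pair5p,pair3p,dg_kcal_mol
AU,AU,-1.1
AU,CG,-2.1
AU,GC,-2.2
AU,GU,-1.4
AU,UA,-0.9
AU,UG,-0.6
CG,AU,-2.1
CG,CG,-2.4
CG,GC,-3.3
CG,GU,-2.1
CG,UA,-2.1
CG,UG,-1.4
GC,AU,-2.2
GC,CG,-3.3
GC,GC,-3.4
GC,GU,-2.5
GC,UA,-2.4
GC,UG,-1.5
GU,AU,-1.4
GU,CG,-2.1
GU,GC,-2.5
GU,GU,1.3
GU,UA,-1.3
GU,UG,-0.5
UA,AU,-0.9
UA,CG,-2.1
UA,GC,-2.4
UA,GU,-1.3
UA,UA,-1.3
UA,UG,-1
UG,AU,-0.6
UG,CG,-1.4
UG,GC,-1.5
UG,GU,-0.5
UG,UA,-1
UG,UG,0.3
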