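segment_class,source,mode,a,b,k,mppe
head,NAS,isometric,NA,NA,1.40,0.20
head,bird,isometric,NA,NA,1.30,0.20
neck,NAS,isometric,NA,NA,2.50,0.20
neck,bird,isometric,NA,NA,1.30,0.20
torso,NAS,isometric,NA,NA,1.50,0.10
torso,bird,isometric,NA,NA,1.70,0.14
tail,NAS,isometric,NA,NA,1.80,0.52
brachium,NAS,isometric,NA,NA,2.00,0.20
brachium,bird,isometric,NA,NA,1.80,0.20
antebrachium,NAS,isometric,NA,NA,1.80,0.20
antebrachium,bird,isometric,NA,NA,1.60,0.20
manus,NAS,isometric,NA,NA,1.40,0.20
manus,bird,isometric,NA,NA,1.30,0.20
thigh,NAS,isometric,NA,NA,2.20,0.20
thigh,bird,isometric,NA,NA,2.40,0.20
shank,NAS,isometric,NA,NA,1.90,0.20
shank,bird,isometric,NA,NA,2.00,0.20
metatarsus,NAS,isometric,NA,NA,1.30,0.20
metatarsus,bird,isometric,NA,NA,1.10,0.20
pes,NAS,isometric,NA,NA,1.40,0.20
pes,bird,isometric,NA,NA,1.20,0.20
head,NAS,allometric,0.14613,1.02,NA,0.20
head,bird,allometric,0.11394,0.98,NA,0.20
neck,NAS,allometric,0.39794,1.03,NA,0.20
neck,bird,allometric,0.11394,0.85,NA,0.20
torso,NAS,allometric,0.17609,1.01,NA,0.10
torso,bird,allometric,0.23045,0.99,NA,0.14
tail,NAS,allometric,0.25527,1.02,NA,0.52
brachium,NAS,allometric,0.30103,1.02,NA,0.20
brachium,bird,allometric,0.25527,0.97,NA,0.20
antebrachium,NAS,allometric,0.25527,1.01,NA,0.20
antebrachium,bird,allometric,0.20412,0.97,NA,0.20
manus,NAS,allometric,0.14613,1.00,NA,0.20
manus,bird,allometric,0.11394,0.96,NA,0.20
thigh,NAS,allometric,0.34242,1.03,NA,0.20
thigh,bird,allometric,0.38021,1.01,NA,0.20
shank,NAS,allometric,0.27875,1.02,NA,0.20
shank,bird,allometric,0.30103,0.99,NA,0.20
metatarsus,NAS,allometric,0.11394,1.00,NA,0.20
metatarsus,bird,allometric,0.04139,0.95,NA,0.20
pes,NAS,allometric,0.14613,1.00,NA,0.20
pes,bird,allometric,0.07918,0.96,NA,0.20
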