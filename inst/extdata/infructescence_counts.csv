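host,host_code,BSLT,LaPerla,Caleria,total
Dieffenbachia oerstedii,Dioe,44,33,0,77
Xanthosoma robustum,Xaro,18,0,0,18
Rhodospatha wendlandii,Rhwe,17,2,0,19
Philodendron inaequilaterum,Phin,0,0,9,9
Philodendron radiatum,Phra,18,0,0,18
Philodendron sagittifolium,Phsa,7,38,0,45
Philodendron seguine,Phse,1,6,4,11
Philodendron tripartitum,Phtr,18,15,20,53
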