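region,source,name
brain,measure,BrainSegVolNotVent
frontal,aparc,superiorfrontal
frontal,aparc,rostralmiddlefrontal
frontal,aparc,caudalmiddlefrontal
frontal,aparc,parsopercularis
frontal,aparc,parstriangularis
frontal,aparc,parsorbitalis
frontal,aparc,lateralorbitofrontal
frontal,aparc,medialorbitofrontal
frontal,aparc,precentral
frontal,aparc,paracentral
temporal,aparc,superiortemporal
temporal,aparc,middletemporal
temporal,aparc,inferiortemporal
temporal,aparc,transversetemporal
temporal,aparc,fusiform
temporal,aparc,entorhinal
temporal,aparc,parahippocampal
parietal,aparc,superiorparietal
parietal,aparc,inferiorparietal
parietal,aparc,supramarginal
parietal,aparc,postcentral
parietal,aparc,precuneus
occipital,aparc,lateraloccipital
occipital,aparc,lingual
occipital,aparc,cuneus
occipital,aparc,pericalcarine
cingulate,aparc,rostralanteriorcingulate
cingulate,aparc,caudalanteriorcingulate
cingulate,aparc,posteriorcingulate
cingulate,aparc,isthmuscingulate
insular,aparc,insula
ventricle,aseg,Left-Lateral-Ventricle
ventricle,aseg,Right-Lateral-Ventricle
ventricle,aseg,Left-Inf-Lat-Vent
ventricle,aseg,Right-Inf-Lat-Vent
ventricle,aseg,3rd-Ventricle
ventricle,aseg,4th-Ventricle
thalamus,aseg,Left-Thalamus-Proper
thalamus,aseg,Right-Thalamus-Proper
putamen,aseg,Left-Putamen
putamen,aseg,Right-Putamen
hippocampus,aseg,Left-Hippocampus
hippocampus,aseg,Right-Hippocampus
caudate,aseg,Left-Caudate
caudate,aseg,Right-Caudate
amygdala,aseg,Left-Amygdala
amygdala,aseg,Right-Amygdala
pallidus,aseg,Left-Pallidum
pallidus,aseg,Right-Pallidum
accumbens,aseg,Left-Accumbens-area
accumbens,aseg,Right-Accumbens-area
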