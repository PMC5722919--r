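event_id,name,region,class2,class4
1,"First oligodendrocyte lineage in spinal cord (ventral)","Spinal cord",A2,A4
2,"Gliogenetic stage in the ventral spinal cord","Spinal cord",A2,A4
3,"Motor neurons expressing Er81","Spinal cord",A2,A4
4,"Parvalbumin-positive fibers reach the ventral horn of the cervical segment","Spinal cord",A2,A4
5,"Olig2- and Pax7-expressing cells derived from dorsal spinal cord","Spinal cord",A2,A4
6,"Myelination in the cervical spinal cord","Spinal cord",A2,A4
7,"Innervation of hindlimb muscle","Spinal cord",A2,A4
8,"Elimination of polyneuronal innervation of hindlimb muscle","Spinal cord",A2,A4
9,"PGP9.5 fibers penetrate the epidermis","DRG",B2,D4
10,"Presumptive low-threshold mechanoreceptor afferent penetrates the spinal gray matter","DRG",B2,D4
11,"Calcitonin gene-related peptide (CGRP)-immunoreactivity in the DRG","DRG",B2,D4
12,"CGRP-positive fibers penetrate the epidermis","DRG",B2,D4
13,"Substance P-positive fibers in the taste buds","DRG",B2,D4
14,"CGRP-positive fibers innervate the heart","DRG",B2,D4
15,"CGRP-positive fibers prominent in the substantia gelatinosa","DRG",B2,D4
16,"Tyrosine hydroxylase (TH)-positive fibers penetrate the cortical plate","Medulla/pons",A2,B4
17,"The first efferent synapse forms below the inner hair cells","Medulla/pons",A2,B4
18,"Axo-somatic synapses between the medial efferent and outer hair cells","Medulla/pons",A2,B4
19,"5-HT-positive fibers innervate the spinal gray matter","Medulla/pons",A2,B4
20,"First 5-HT-positive cells","Medulla/pons",A2,B4
21,"First appearance of noradrenergic cells","Medulla/pons",A2,B4
22,"Diffuse staining of Sonic hedgehog (Shh) in the inner region of the cerebellum","Cerebellum",B2,C4
23,"The first IP3R1-positive cells in the Purkinje cell layer","Cerebellum",B2,C4
24,"Synapse formation between climbing fibers and Purkinje cells","Cerebellum",B2,C4
25,"First PV-positive Purkinje cells","Cerebellum",B2,C4
26,"Shh-reactive cells disappear in the external granule layer","Cerebellum",B2,C4
27,"Young climbing phase in lateral hemisphere of cerebellum","Cerebellum",B2,C4
28,"TH-positive cells in the midbrain","Midbrain",A2,A4
29,"Brn3a-positive cells in the ventral mesencephalon","Midbrain",A2,A4
30,"Catecholamine fibers innervate the habenula region","Midbrain",A2,A4
31,"GAP-43 expression declines in the superior colliculus","Midbrain",A2,A4
32,"TH-positive cells in the zona incerta (A13)","Thalamus",A2,A4
33,"Calbindin-positive cells and processes in the anteroventral thalamus","Thalamus",A2,A4
34,"PV-positive cells in the reticular thalamus","Thalamus",A2,A4
35,"GABAergic interneurons in dorsal lateral geniculate nucleus (the dLGN)","Thalamus",A2,A4
36,"Dendrodendritic contact in dLGN","Thalamus",A2,A4
37,"Thyrotropin-releasing hormone (TRH)-positive cells in the hypothalamus","Hypothalamus",B2,D4
38,"Neurophysin-positive cells in the paraventricular hypothalamus","Hypothalamus",B2,D4
39,"Calbindin-positive cells first appear in the lateral hypothalamus","Hypothalamus",B2,D4
40,"Somatostatin-positive neurons first appear in the hypothalamus","Hypothalamus",B2,D4
41,"Corticotropin-releasing hormone (CRH)-positive cells first appear in the hypothalamus","Hypothalamus",B2,D4
42,"Melatonin binding site in the suprachiasmatic nuclei","Hypothalamus",B2,D4
43,"Neurophysin-positive cells in the suprachiasmatic nuclei","Hypothalamus",B2,D4
44,"Neuropeptide-Y staining in the arcuate nucleus","Hypothalamus",B2,D4
45,"Calbindin-positive mammillothalamic tract fibers penetrate the ventral anterior thalamus","Hypothalamus",B2,D4
46,"Galamin-positive cells in the mammillary nucleus","Hypothalamus",B2,D4
47,"Arginine vasopressin (AVP)-staining in the suprachiasmatic nuclei","Hypothalamus",B2,D4
48,"Isl1-ir in the lateral ganglionic eminence","Subcortex",B2,C4
49,"First acetylcholinesterase (AChE)-reactive neurons in the basal forebrain","Subcortex",B2,C4
50,"External Capsule AChE reactive","Subcortex",B2,C4
51,"AChE-positive fibers penetrate the stratum oriens in the hippocampus","Subcortex",B2,C4
52,"Myelination begin in the caudate-putamen","Subcortex",B2,C4
53,"The secondary dentate matrix forms in the hippocampus","Allocortex",B2,D4
54,"Tbr2-positive Cajal-Retzius cells first appear in the hippocampus","Allocortex",B2,D4
55,"The primary germinal matrix of the dentate gyrus disappears","Allocortex",B2,D4
56,"Calbindin-positive multipolar neurons in the claustrum/amygdala","Allocortex",B2,D4
57,"Calbindin immunoreactivity in the str.lucidum along the whole CA3 region except CA3c","Allocortex",B2,D4
58,"Calbindin immunoreactivity in the str.lucidum along the whole CA3 region including the CA3c","Allocortex",B2,D4
59,"Anterior commissure fibers cross the midline","Allocortex",B2,D4
60,"Glomeruli formation in the olfactory bulb","Allocortex",B2,D4
61,"First Reelin-positive cells in the marginal zone","Isocortex",B2,C4
62,"Calretinin-positive pioneer cells in the marginal zone","Isocortex",B2,C4
63,"First GABAergic neurons in the lateral cortical wall","Isocortex",B2,C4
64,"DARPP32-positive cells detected in the pallium, but not in the striatum","Isocortex",B2,C4
65,"Cortical plate formation","Isocortex",B2,C4
66,"Callosal fibers cross the midline","Isocortex",B2,C4
67,"ER81 or Er81-positive layer V band","Isocortex",B2,C4
68,"Npn1-positive cingulate pioneer axons","Isocortex",B2,C4
69,"Ontogeny of KCC2-positive neurons in the cortical plate","Isocortex",B2,C4
70,"Excitatory GABAergic response in cortical layer I","Isocortex",B2,C4
71,"Reelin-positive cells below the cortical surface with ascending fibers","Isocortex",B2,C4
72,"Corticospinal neurons innervate cervical spinal motor neurons","Isocortex",B2,C4
73,"Mediodorsal thalamus fibers form two intense bands in cortical layer VI","Isocortex",B2,C4
74,"Switch from bursting to acuity in the light response","Isocortex",B2,C4
75,"Radial glial processes disappear in the cerebral cortex","Isocortex",B2,C4
76,"Nrl expression in the retina","Retina",A2,B4
77,"Synaptophysin in the inner plexiform layer","Retina",A2,B4
78,"Rod opsin expression in the retina","Retina",A2,B4
79,"Synaptophysin in the outer plexiform layer","Retina",A2,B4
80,"Airways are covered with smooth muscle and enveloped by nerve trunks","Other 1",A2,
81,"Open tunnel of Corti","Other 2",A2,
82,"Eyes opening","Other 3",A2,
83,"Gonadotropin-releasing hormone-positive cells first detected in the vomeronasal organ","Vomeronasal organ",B2,
84,"Myelination begins in the optic nerve at chiasm","Optic nerve",B2,
85,"Ossification of maxilla","Skeleton",A2,
86,"Ossification of nasal","Skeleton",A2,
87,"Ossification of supraoccipital","Skeleton",A2,
88,"Merkel cells in the skin","Other 4",A2,
89,"Nerve fibers penetrate the tongue epithelium","Other 5",A2,
90,"Neuropeptide Y-positive fibers innervate the heart","Other 6",A2,
91,"Onset of hair follicle bulge","Other 7",B2,
92,"Onset of arrector pili muscles","Other 8",B2,
93,"Eyelash growth","Other 9",B2,
94,"Birth date","Other 10",,
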