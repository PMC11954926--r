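tissue	tissue_type
Adipose - Subcutaneous	Adipose Tissue
Adipose - Visceral (Omentum)	Adipose Tissue
Adrenal Gland	Adrenal Gland
Artery - Aorta	Blood Vessel
Artery - Coronary	Blood Vessel
Artery - Tibial	Blood Vessel
Brain - Amygdala	Brain
Brain - Anterior cingulate cortex (BA24)	Brain
Brain - Caudate (basal ganglia)	Brain
Brain - Cerebellar Hemisphere	Brain
Brain - Cerebellum	Brain
Brain - Cortex	Brain
Brain - Frontal Cortex (BA9)	Brain
Brain - Hippocampus	Brain
Brain - Hypothalamus	Brain
Brain - Nucleus accumbens (basal ganglia)	Brain
Brain - Putamen (basal ganglia)	Brain
Brain - Spinal cord (cervical c-1)	Brain
Brain - Substantia nigra	Brain
Breast - Mammary Tissue	Breast
Cells - Cultured fibroblasts	Skin
Cells - EBV-transformed lymphocytes	Blood
Colon - Sigmoid	Colon
Colon - Transverse	Colon
Esophagus - Gastroesophageal Junction	Esophagus
Esophagus - Mucosa	Esophagus
Esophagus - Muscularis	Esophagus
Heart - Atrial Appendage	Heart
Heart - Left Ventricle	Heart
Kidney - Cortex	Kidney
Liver	Liver
Lung	Lung
Minor Salivary Gland	Salivary Gland
Muscle - Skeletal	Muscle
Nerve - Tibial	Nerve
Ovary	Ovary
Pancreas	Pancreas
Pituitary	Pituitary
Prostate	Prostate
Skin - Not Sun Exposed (Suprapubic)	Skin
Skin - Sun Exposed (Lower leg)	Skin
Small Intestine - Terminal Ileum	Small Intestine
Spleen	Spleen
Stomach	Stomach
Testis	Testis
Thyroid	Thyroid
Uterus	Uterus
Vagina	Vagina
Whole Blood	Blood
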