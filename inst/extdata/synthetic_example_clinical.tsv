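patient_id	cancer_type	sample_type	ajcc_pathologic_t	ajcc_pathologic_n	ajcc_pathologic_m	ajcc_clinical_m	gender
TCGA-01-0001	SYN1	Primary Tumor	T1	N1	M0	M0	male
TCGA-01-0002	SYN1	Primary Tumor	T4	N1	M1	M1	male
TCGA-01-0003	SYN1	Primary Tumor	T4	N0	M0	M0	male
TCGA-01-0004	SYN1	Primary Tumor	T4	N0	M0	M0	female
TCGA-01-0005	SYN1	Primary Tumor	T1	N1	M1	M1	female
TCGA-01-0006	SYN1	Primary Tumor	T1	N0	M1	M1	female
TCGA-01-0007	SYN1	Primary Tumor	T1	N0	M1	M1	male
TCGA-01-0008	SYN1	Primary Tumor	T4	N1	M0	M0	female
TCGA-02-0001	SYN2	Primary Tumor	T1	N0	M1	M1	female
TCGA-02-0002	SYN2	Primary Tumor	T4	N0	M0	M0	female
TCGA-02-0003	SYN2	Primary Tumor	T4	N1	M1	M1	male
TCGA-02-0004	SYN2	Primary Tumor	T4	N1	M0	M0	female
TCGA-02-0005	SYN2	Primary Tumor	T1	N1	M0	M0	male
TCGA-02-0006	SYN2	Primary Tumor	T1	N0	M1	M1	male
TCGA-02-0007	SYN2	Primary Tumor	T1	N0	M0	M0	male
TCGA-02-0008	SYN2	Primary Tumor	T4	N1	M1	M1	female
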