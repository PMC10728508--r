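# Template configuration for inst/cli/run_all.R. All keys optional;
# command-line flags override file values.

# "simulate" generates a synthetic cohort; "seg_files" ingests real tables.
mode: simulate

# --- simulate mode -----------------------------------------------------
genome: toy            # "toy" (3 chromosomes, fast) or "default" (22 autosomes)
cancer_types: [SYN1, SYN2]
n_per_group: 25        # patients per level of each clinical contrast
breakpoint_rate: 0.05  # expected breakpoints per Mb per sample
p_alt: 0.1             # baseline probability a segment is aberrant
alt_mean: 0.5          # aberrant amplitude location (log2-ratio units)
alt_sd: 0.1            # aberrant amplitude spread
neutral_sd: 0.05       # neutral segment-mean noise
paired_normal: true    # also emit a matched normal sample per patient
seed: 1

# --- seg_files mode ----------------------------------------------------
# seg_files: [cohort1.seg, cohort2.seg]
# clinical_file: clinical.tsv
# m_attribute: ajcc_pathologic_m   # use ajcc_clinical_m for ACC

# --- analysis ----------------------------------------------------------
aberration_threshold: 0.2   # |segment mean| >= t counts as aberrant
adjacency_difference: 0.2   # CNA neighbour separation d
min_group_size: 3
top_k: 10
skip_invalid: false
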