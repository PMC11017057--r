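# Published demographic summary statistics (aggregate values) from a
# multi-site schizophrenia case-control MRI-genetics consortium sample.
# Quantitative rows: group sizes, means, SDs (test = F, two-group ANOVA
# from summaries). The sex row stores female/male counts per group
# (test = chi2, Pearson 2x2 without continuity correction).
variable	test	case_n	case_mean	case_sd	control_n	control_mean	control_sd	case_n_female	case_n_male	control_n_female	control_n_male
age_years	F	720	35.2	11.8	912	35.9	12.9	NA	NA	NA	NA
education_years	F	671	12.5	2.7	702	14.5	2.4	NA	NA	NA	NA
premorbid_iq	F	373	103	14.4	388	111.8	10.7	NA	NA	NA	NA
current_iq	F	365	99.4	16.6	410	116.9	14	NA	NA	NA	NA
sex	chi2	720	NA	NA	912	NA	NA	208	512	439	473
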