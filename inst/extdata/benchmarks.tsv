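name	dim	lower_bound	upper_bound	printed_optimum	category
F1	30	-100	100	0	unimodal
F2	30	-10	10	0	unimodal
F3	30	-100	100	0	unimodal
F4	30	-100	100	0	unimodal
F5	30	-30	30	0	unimodal
F6	30	-100	100	0	unimodal
F7	30	-1.28	1.28	0	unimodal
F8	30	-500	500	-12569.487	multimodal
F9	30	-5.12	5.12	0	multimodal
F10	30	-32	32	0	multimodal
F11	30	-600	600	0	multimodal
F12	30	-50	50	0	multimodal
F13	30	-50	50	0	multimodal
F14	2	-65.536	65.536	1	fixed_dimension_multimodal
F15	4	-5	5	3e-04	fixed_dimension_multimodal
F16	2	-5	5	-1.0316	fixed_dimension_multimodal
F17	2	-5	5	0.398	fixed_dimension_multimodal
F18	2	-2	2	3	fixed_dimension_multimodal
F19	3	0	1	-3.86	fixed_dimension_multimodal
F20	6	0	1	-3.32	fixed_dimension_multimodal
F21	4	0	10	-10.1532	fixed_dimension_multimodal
F22	4	0	10	-10.4028	fixed_dimension_multimodal
F23	4	0	10	-10.5363	fixed_dimension_multimodal
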