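construct_id	trait	mean	sd	n	marked
NtLs	expression	0.50	0.08	3	FALSE
NtLs	primary_n	1.00	0.00	3	FALSE
NtLs	primary_wt	1.28	0.15	3	FALSE
NtLs	secondary_n	0.13	0.09	3	TRUE
NtLs	secondary_wt	0.10	0.06	3	TRUE
NtBl1	expression	0.31	0.05	3	FALSE
NtBl1	primary_n	1.02	0.06	3	FALSE
NtBl1	primary_wt	1.21	0.18	3	FALSE
NtBl1	secondary_n	0.00	0.00	3	TRUE
NtBl1	secondary_wt	0.00	0.00	3	TRUE
NtBl2	expression	0.19	0.04	3	FALSE
NtBl2	primary_n	1.00	0.00	3	FALSE
NtBl2	primary_wt	1.13	0.15	3	FALSE
NtBl2	secondary_n	1.00	0.10	3	FALSE
NtBl2	secondary_wt	1.46	1.65	3	FALSE
NtBl3	expression	0.30	0.09	3	FALSE
NtBl3	primary_n	1.00	0.00	3	FALSE
NtBl3	primary_wt	1.45	0.48	3	FALSE
NtBl3	secondary_n	0.88	0.46	3	FALSE
NtBl3	secondary_wt	0.77	0.12	3	FALSE
NtREV	expression	0.62	0.10	3	FALSE
NtREV	primary_n	1.00	0.00	3	FALSE
NtREV	primary_wt	0.98	0.09	3	FALSE
NtREV	secondary_n	0.06	0.10	3	TRUE
NtREV	secondary_wt	0.03	0.04	3	TRUE
NtCUC1	expression	0.16	0.07	3	FALSE
NtCUC1	primary_n	1.00	0.00	3	FALSE
NtCUC1	primary_wt	1.05	0.12	3	FALSE
NtCUC1	secondary_n	0.91	0.18	3	FALSE
NtCUC1	secondary_wt	0.57	0.10	3	FALSE
NtCUC2	expression	0.53	0.04	3	FALSE
NtCUC2	primary_n	1.00	0.00	3	FALSE
NtCUC2	primary_wt	1.14	0.26	3	FALSE
NtCUC2	secondary_n	0.97	0.12	3	FALSE
NtCUC2	secondary_wt	1.06	0.40	3	FALSE
NtCUC3	expression	0.17	0.10	3	FALSE
NtCUC3	primary_n	1.00	0.00	3	FALSE
NtCUC3	primary_wt	0.96	0.17	3	FALSE
NtCUC3	secondary_n	1.08	0.01	3	FALSE
NtCUC3	secondary_wt	0.71	0.26	3	FALSE
NtCUC4	expression	0.69	0.03	3	FALSE
NtCUC4	primary_n	1.00	0.00	3	FALSE
NtCUC4	primary_wt	0.91	0.04	3	FALSE
NtCUC4	secondary_n	1.05	0.09	3	FALSE
NtCUC4	secondary_wt	0.75	0.19	3	FALSE
NtFHY3	expression	0.31	0.17	3	FALSE
NtFHY3	primary_n	1.00	0.00	3	FALSE
NtFHY3	primary_wt	0.94	0.08	3	FALSE
NtFHY3	secondary_n	1.03	0.11	3	FALSE
NtFHY3	secondary_wt	1.12	0.62	3	FALSE
NtLOM1	expression	0.38	0.06	3	FALSE
NtLOM1	primary_n	1.00	0.00	3	FALSE
NtLOM1	primary_wt	1.09	0.15	3	FALSE
NtLOM1	secondary_n	1.72	1.97	3	FALSE
NtLOM1	secondary_wt	2.56	3.99	3	FALSE
NtLOF1	expression	0.38	0.11	3	FALSE
NtLOF1	primary_n	1.01	0.02	3	FALSE
NtLOF1	primary_wt	1.67	0.15	3	FALSE
NtLOF1	secondary_n	0.28	0.30	3	FALSE
NtLOF1	secondary_wt	0.64	0.58	3	FALSE
EA1	expression	0.09	0.03	3	FALSE
EA1	primary_n	1.00	0.00	3	FALSE
EA1	primary_wt	1.14	0.16	3	FALSE
EA1	secondary_n	0.97	0.15	3	FALSE
EA1	secondary_wt	1.21	0.34	3	FALSE
EA2	expression	0.28	0.16	3	FALSE
EA2	primary_n	1.00	0.00	3	FALSE
EA2	primary_wt	1.17	0.35	3	FALSE
EA2	secondary_n	1.34	0.82	3	FALSE
EA2	secondary_wt	1.65	1.59	3	FALSE
EA3	expression	0.16	0.03	3	FALSE
EA3	primary_n	1.00	0.00	3	FALSE
EA3	primary_wt	0.93	0.09	3	FALSE
EA3	secondary_n	0.68	0.16	3	FALSE
EA3	secondary_wt	1.42	1.53	3	FALSE
EA4	expression	0.35	0.17	3	FALSE
EA4	primary_n	1.00	0.00	3	FALSE
EA4	primary_wt	1.16	0.28	3	FALSE
EA4	secondary_n	1.14	0.41	3	FALSE
EA4	secondary_wt	1.09	0.38	3	FALSE
EA5	expression	0.10	0.04	3	FALSE
EA5	primary_n	1.00	0.00	3	FALSE
EA5	primary_wt	1.04	0.07	3	FALSE
EA5	secondary_n	4.05	2.21	3	FALSE
EA5	secondary_wt	18.88	28.34	3	FALSE
EA6	expression	0.80	0.22	3	FALSE
EA6	primary_n	1.00	0.00	3	FALSE
EA6	primary_wt	1.01	0.26	3	FALSE
EA6	secondary_n	1.04	0.27	3	FALSE
EA6	secondary_wt	1.30	0.80	3	FALSE
EA7	expression	0.10	0.01	3	FALSE
EA7	primary_n	1.00	0.00	3	FALSE
EA7	primary_wt	1.02	0.17	3	FALSE
EA7	secondary_n	0.83	0.76	3	FALSE
EA7	secondary_wt	0.77	0.70	3	FALSE
EA8	expression	0.02	0.02	3	FALSE
EA8	primary_n	1.00	0.00	3	FALSE
EA8	primary_wt	1.08	0.36	3	FALSE
EA8	secondary_n	1.14	0.11	3	FALSE
EA8	secondary_wt	1.21	0.20	3	FALSE
EA9	expression	0.17	0.12	3	FALSE
EA9	primary_n	1.00	0.00	3	FALSE
EA9	primary_wt	0.95	0.17	3	FALSE
EA9	secondary_n	1.10	0.77	3	FALSE
EA9	secondary_wt	1.16	0.74	3	FALSE
EA10	expression	0.43	0.08	3	FALSE
EA10	primary_n	1.00	0.00	3	FALSE
EA10	primary_wt	1.33	0.16	3	FALSE
EA10	secondary_n	1.59	0.99	3	FALSE
EA10	secondary_wt	0.96	0.21	3	FALSE
EA11	expression	0.56	0.08	3	FALSE
EA11	primary_n	1.00	0.00	3	FALSE
EA11	primary_wt	0.98	0.27	3	FALSE
EA11	secondary_n	0.98	0.09	3	FALSE
EA11	secondary_wt	1.52	0.92	3	FALSE
VE1	expression	0.58	0.06	3	FALSE
VE1	primary_n	1.00	0.00	3	FALSE
VE1	primary_wt	0.99	0.30	3	FALSE
VE1	secondary_n	1.10	0.16	3	FALSE
VE1	secondary_wt	1.27	0.51	3	FALSE
VE2	expression	0.51	0.02	3	FALSE
VE2	primary_n	1.00	0.00	3	FALSE
VE2	primary_wt	1.04	0.12	3	FALSE
VE2	secondary_n	1.09	0.17	3	FALSE
VE2	secondary_wt	0.95	0.54	3	FALSE
VE3	expression	1.51	0.05	3	FALSE
VE3	primary_n	1.00	0.00	3	FALSE
VE3	primary_wt	1.16	0.21	3	FALSE
VE3	secondary_n	1.02	0.45	3	FALSE
VE3	secondary_wt	0.97	0.35	3	FALSE
VE4	expression	0.32	0.04	3	FALSE
VE4	primary_n	1.00	0.00	3	FALSE
VE4	primary_wt	1.27	0.31	3	FALSE
VE4	secondary_n	0.80	0.38	3	FALSE
VE4	secondary_wt	0.95	0.64	3	FALSE
VE5	expression	0.41	0.06	3	FALSE
VE5	primary_n	1.00	0.00	3	FALSE
VE5	primary_wt	1.00	0.17	3	FALSE
VE5	secondary_n	1.30	0.74	3	FALSE
VE5	secondary_wt	1.41	0.84	3	FALSE
VE6	expression	0.35	0.14	3	FALSE
VE6	primary_n	1.00	0.00	3	FALSE
VE6	primary_wt	0.73	0.12	3	FALSE
VE6	secondary_n	2.06	0.56	3	FALSE
VE6	secondary_wt	4.57	3.20	3	FALSE
VE7	expression	0.08	0.02	3	FALSE
VE7	primary_n	1.00	0.00	3	FALSE
VE7	primary_wt	1.49	0.30	3	FALSE
VE7	secondary_n	0.33	0.09	3	TRUE
VE7	secondary_wt	0.26	0.11	3	TRUE
VE8	expression	0.14	0.06	3	FALSE
VE8	primary_n	1.00	0.00	3	FALSE
VE8	primary_wt	1.01	0.28	3	FALSE
VE8	secondary_n	1.41	0.43	3	FALSE
VE8	secondary_wt	0.87	0.39	3	FALSE
VE9	expression	0.62	0.08	3	FALSE
VE9	primary_n	1.00	0.00	3	FALSE
VE9	primary_wt	0.98	0.10	3	FALSE
VE9	secondary_n	1.03	0.16	3	FALSE
VE9	secondary_wt	0.90	0.12	3	FALSE
VE10	expression	0.42	0.04	3	FALSE
VE10	primary_n	1.00	0.00	3	FALSE
VE10	primary_wt	0.97	0.25	3	FALSE
VE10	secondary_n	1.16	0.62	3	FALSE
VE10	secondary_wt	1.79	1.29	3	FALSE
VE11	expression	0.70	0.07	3	FALSE
VE11	primary_n	1.00	0.00	3	FALSE
VE11	primary_wt	1.07	0.28	3	FALSE
VE11	secondary_n	0.58	0.56	3	FALSE
VE11	secondary_wt	0.42	0.43	3	FALSE
VE12	expression	0.18	0.06	3	FALSE
VE12	primary_n	1.00	0.00	3	FALSE
VE12	primary_wt	1.22	0.12	3	FALSE
VE12	secondary_n	0.29	0.41	3	FALSE
VE12	secondary_wt	0.05	0.08	3	TRUE
VE13	expression	0.14	0.05	3	FALSE
VE13	primary_n	1.00	0.00	3	FALSE
VE13	primary_wt	1.03	0.21	3	FALSE
VE13	secondary_n	1.03	0.12	3	FALSE
VE13	secondary_wt	1.86	0.94	3	FALSE
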