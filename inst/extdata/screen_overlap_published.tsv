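gene	p	direction	direct_interactor
MOB4	0.003	larger	TRUE
PSMA1	0.014	smaller	FALSE
TCP1	0.014	larger	TRUE
NOP56	0.014	smaller	FALSE
CCT8	0.015	larger	TRUE
ACTB	0.018	larger	FALSE
RPL10L	0.033	smaller	FALSE
RPL9	0.058	smaller	FALSE
ATP6V1B2	0.064	smaller	FALSE
HSPA8	0.065	larger	FALSE
RPL22	0.087	smaller	FALSE
PSMB3	0.089	smaller	FALSE
RPL11	0.097	smaller	FALSE
RPS13	0.12	smaller	FALSE
PSMC2	0.131	smaller	FALSE
PSMD1	0.137	smaller	FALSE
PRPF8	0.141	smaller	TRUE
ACTR2	0.153	larger	FALSE
ACTG1	0.159	larger	TRUE
PLRG1	0.168	smaller	FALSE
SCFD1	0.189	smaller	FALSE
AP1M1	0.196	smaller	FALSE
RRP15	0.199	larger	FALSE
U2AF1	0.199	smaller	FALSE
RPS12	0.233	smaller	FALSE
SNW1	0.253	larger	FALSE
RPSA	0.272	smaller	FALSE
ARCN1	0.289	smaller	FALSE
SCD	0.289	larger	FALSE
ATP5B	0.299	larger	FALSE
RPS19	0.31	smaller	FALSE
RPS16	0.313	smaller	FALSE
DARS	0.314	smaller	FALSE
RPL8	0.322	smaller	FALSE
STX5	0.33	smaller	FALSE
POLR2A	0.331	smaller	FALSE
GSPT2	0.333	larger	FALSE
EIF3G	0.334	larger	FALSE
DNAJC3	0.343	smaller	FALSE
PSMC5	0.346	smaller	TRUE
CPSF2	0.362	smaller	FALSE
SEC23B	0.371	larger	FALSE
RAB1A	0.382	smaller	FALSE
SF3B1	0.421	smaller	FALSE
PRKAR1A	0.435	smaller	FALSE
RPS3	0.437	smaller	FALSE
OGDHL	0.449	larger	FALSE
SNRPD3	0.458	smaller	FALSE
ACSF2	0.467	larger	FALSE
NDUFA6	0.486	larger	FALSE
UBA6	0.515	larger	FALSE
CRNKL1	0.535	larger	FALSE
MAT1A	0.539	smaller	FALSE
RPL36AL	0.55	larger	FALSE
ATP6V1A	0.557	larger	FALSE
SERINC1	0.577	larger	FALSE
EIF2B5	0.58	smaller	FALSE
HIST1H2BA	0.58	smaller	FALSE
AP1S2	0.655	smaller	FALSE
ATP6V0C	0.759	larger	FALSE
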