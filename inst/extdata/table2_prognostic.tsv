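gene	direction	p_dmfs	p_os	p_rfs
ABCA12	worse	3e-4	8e-4	7.9e-3
ADAM9	worse	1.3e-7	3.8e-5	4.6e-13
ARTN	worse	7.5e-3	3.8e-2	3.1e-3
CD24	worse	1.4e-7	9.2e-7	4e-12
CDH2	worse	1.2e-4	8.3e-6	4.2e-7
CKMT1A	worse	2.1e-16	3.6e-8	7.8e-14
CKMT1B	worse	2.1e-16	3.6e-8	7.8e-14
CLDN1	worse	9.7e-5	2.1e-2	4.5e-5
CLDN3	worse	2e-2	7.4e-4	6.4e-5
CLDN4	worse	9.5e-3	3e-3	1.2e-2
CLDN7	worse	5.3e-6	2.1e-4	7.3e-3
EPCAM	worse	4.5e-6	2.1e-4	<1e-16
ESRP1	worse	3.9e-7	3.7e-5	8e-14
ESRP2	worse	5.4e-4	4.5e-5	3.4e-4
FN1	worse	9.7e-4	2.9e-2	5e-3
GREM1	worse	4.6e-7	2.4e-3	5.6e-11
ITGB1	worse	1e-3	5.5e-3	1.1e-9
KRT16	worse	9.8e-9	1.5e-5	9e-15
LAD1	worse	4.4e-11	2.4e-4	1.4e-8
LAMA3	worse	4.9e-2	1.8e-2	7.1e-3
LTBP1	worse	2e-7	1.4e-2	1.6e-6
MGAT5B	worse	1.2e-2	1.2e-2	2.1e-5
MT2A	worse	3.8e-5	8.2e-5	8.5e-7
NDRG1	worse	4.6e-11	3.4e-7	<1e-16
PLP2	worse	2.7e-4	8e-3	3e-11
S100A8	worse	6.9e-9	6.8e-6	1.3e-12
SERPINE1	worse	4.1e-3	2.5e-2	1.7e-5
SLPI	worse	1.4e-6	4.5e-4	8.3e-6
SNAI1	worse	1.8e-7	1.6e-4	7.4e-4
ST14	worse	1.6e-5	1.5e-6	4.6e-9
TCF3	worse	1.5e-4	1.8e-3	6.6e-6
TGFB1	worse	3.6e-2	4.6e-2	1.6e-2
THY1	worse	1.8e-3	5.4e-3	3.7e-3
ALDH1A1	better	1.1e-6	5e-8	8.2e-10
AXL	better	3.8e-2	1.4e-2	1.3e-4
CD44	better	3.6e-8	7.9e-5	3e-13
CDH1	better	3.2e-2	4e-2	3.5e-6
COL17A1	better	2.5e-3	7.8e-4	8e-16
COL6A1	better	3.3e-2	3.6e-3	1.1e-4
CORO1A	better	1.7e-3	3.1e-4	2.3e-3
DCN	better	8.7e-5	3.4e-3	1.7e-4
ERBB3	better	2.6e-3	5.8e-4	7.9e-5
ESR1	better	<1e-16	2.2e-7	<1e-16
FBLN5	better	1.1e-2	5.3e-4	5.9e-7
FGFR2	better	1.8e-11	1.2e-8	3.1e-11
FST	better	4.4e-2	1.8e-2	5e-7
ITGBL1	better	7.6e-3	5.2e-3	4e-7
KCNMA1	better	8.2e-5	4.5e-5	1.7e-8
KRT14	better	1.2e-4	2.8e-3	6.8e-7
LIFR	better	4.4e-4	5.3e-8	4.5e-9
MLPH	better	2.2e-8	3.9e-3	<1e-16
NR2F1	better	2.2e-2	1.6e-2	4.2e-2
PLAT	better	5.9e-10	2.1e-4	1.1e-11
PRKCH	better	1.4e-3	8.3e-3	1.6e-9
S100A14	better	2.9e-2	6e-3	6.2e-3
SAA1	better	1.8e-5	4.2e-3	6.6e-5
SEMA5A	better	1.9e-2	1.3e-2	5.6e-6
SERPINB1	better	1.5e-4	1.4e-3	<1e-16
TBX3	better	1.8e-4	5.7e-4	3.1e-10
TFPI	better	4.3e-2	5.5e-5	5.4e-3
TP63	better	3.7e-2	2.4e-3	3.5e-10
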