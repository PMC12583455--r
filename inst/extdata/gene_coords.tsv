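gene	chrom	start	end
TERC	3	169764520	169765060
TERT	5	1253280	1295190
TINF2	14	24708850	24711880
DKC1	X	154762740	154777690
RTEL1	20	63657800	63696360
PARN	16	14529550	14724120
NAF1	4	163106480	163166120
ZCCHC8	12	122497870	122529340
SFTPC	8	22159170	22164480
SFTPA2	10	79884340	79888860
ABCA3	16	2275880	2340720
SFTPA1	10	79935670	79940350
SPDL1	5	169588550	169611250
KIF15	3	44761490	44849190
MUC5B	11	1223060	1262170
ACTRT3	3	169767760	169776920
AKAP13	15	85369340	85739290
MAD1L1	7	1815790	2232950
RAPGEF2	4	159084110	159344530
SFTPD	10	79934390	79946790
HPS1	10	98415950	98446570
HPS3	3	149121230	149165860
HPS4	22	26443830	26483230
GLA	X	101397800	101407920
DPP9	19	4675240	4723850
FAM111B	11	59149820	59159450
TSC1	9	132891350	132944640
TSC2	16	2047980	2088720
LIG4	13	108199350	108207480
WRAP53	17	7591690	7607780
NOP10	15	34338210	34339060
NHP2	5	178149950	178154960
POT1	7	124822380	124929820
TERF1	8	73008890	73048120
TERF2	16	69355290	69385740
TERF2IP	16	75681680	75795770
ACD	16	67657060	67660910
CTC1	17	8224820	8248130
STN1	10	103916100	103952070
TEN1	17	75495200	75499820
RPA1	17	1732550	1802850
ZNF208	19	22148880	22193750
BGND1	1	10000000	10050000
BGND2	2	20000000	20060000
BGND3	6	30000000	30045000
BGND4	9	40000000	40052000
BGND5	12	50000000	50048000
BGND6	18	60000000	60041000
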