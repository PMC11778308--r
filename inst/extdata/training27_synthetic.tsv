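accession	regulatory_index	acquisition_index	label
TRAIN_RUD_01	0.0882979772907242	0.47519824858635	ruderal
TRAIN_RUD_02	0.0604258265422212	0.328558898426322	ruderal
TRAIN_RUD_03	0.0644456599165163	0.517340142650458	ruderal
TRAIN_RUD_04	0.0667016563909056	0.482516154079165	ruderal
TRAIN_RUD_05	0.0622346132710441	0.325921643211081	ruderal
TRAIN_RUD_06	0.0624217604381751	0.451685365344794	ruderal
TRAIN_RUD_07	0.0759851147223244	0.337414440905736	ruderal
TRAIN_RUD_08	0.0690643581929028	0.228495942153164	ruderal
TRAIN_RUD_09	0.0712212610102579	0.275413736037024	ruderal
TRAIN_COM_01	0.0399710654663946	1.28876175786941	competitor
TRAIN_COM_02	0.0459289848969997	1.05254211063435	competitor
TRAIN_COM_03	0.0450385021577444	1.1585904067332	competitor
TRAIN_COM_04	0.044232050985433	1.06937234661471	competitor
TRAIN_COM_05	0.0478357883248701	1.30780658296264	competitor
TRAIN_COM_06	0.0316720227004429	1.2165979316654	competitor
TRAIN_COM_07	0.0476375011855314	1.18822998480424	competitor
TRAIN_COM_08	0.0411051566274146	1.1369264310987	competitor
TRAIN_COM_09	0.0445136793744402	1.11568111855721	competitor
TRAIN_SCA_01	0.0219900537790212	0.129923669345251	scarcity
TRAIN_SCA_02	0.0135794797647469	0.217525879046148	scarcity
TRAIN_SCA_03	0.0174308486769017	0.179559501354461	scarcity
TRAIN_SCA_04	0.0192599796195517	0.155026272781428	scarcity
TRAIN_SCA_05	0.0228742021380294	0.196553599776005	scarcity
TRAIN_SCA_06	0.0152027316852579	0.136862882571673	scarcity
TRAIN_SCA_07	0.0168582689938851	0.149616594764367	scarcity
TRAIN_SCA_08	0.0127537893095625	0.168357650327282	scarcity
TRAIN_SCA_09	0.016435950274203	0.23535812725688	scarcity
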