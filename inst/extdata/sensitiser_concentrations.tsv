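chemical	cas	context	medium	value	unit	provenance
phthalic anhydride	85-44-9	in_vitro_epithelial	culture medium	1330	uM	16HBE14o epithelial cells, 4 h exposure at 80% viability
phthalic anhydride	85-44-9	in_vitro_dendritic	culture medium	200	uM	MUTZ-3 dendritic cells, 24 h exposure
phthalic anhydride	85-44-9	in_vivo_biomonitoring	urine	2460	uM	occupational urinary biomonitoring, range low end (0.3 umol/mmol creatinine)
phthalic anhydride	85-44-9	in_vivo_biomonitoring	urine	114800	uM	occupational urinary biomonitoring, range high end (14.0 umol/mmol creatinine)
glutaraldehyde	111-30-8	in_vitro_epithelial	culture medium	190	uM	16HBE14o epithelial cells, 4 h exposure at 80% viability
glutaraldehyde	111-30-8	in_vitro_dendritic	culture medium	10	uM	MUTZ-3 dendritic cells, 24 h exposure
glutaraldehyde	111-30-8	in_vivo_predicted	plasma	0.08	uM	generic PBK plasma Cmax, dermal scenario, low end
glutaraldehyde	111-30-8	in_vivo_predicted	plasma	0.16	uM	generic PBK plasma Cmax, dermal scenario, high end
2,4-Diisocyanato-1-methylbenzene	584-84-9	in_vitro_epithelial	culture medium	150	uM	16HBE14o epithelial cells, 4 h exposure at 80% viability
2,4-Diisocyanato-1-methylbenzene	584-84-9	in_vitro_dendritic	culture medium	40	uM	MUTZ-3 dendritic cells, 24 h exposure
2,4-Diisocyanato-1-methylbenzene	584-84-9	in_vivo_predicted	lung interstitial fluid	0.023	uM	inhalation PBK model, 40 ug/m3 for 4 h
2,4-Diisocyanato-1-methylbenzene	584-84-9	in_vivo_predicted	lung epithelial lining fluid	0.000575	uM	inhalation PBK model, single inhalation at 40 ug/m3
maleic anhydride	24937-72-2	in_vitro_epithelial	culture medium	2650	uM	16HBE14o epithelial cells, 4 h exposure at 80% viability
maleic anhydride	24937-72-2	in_vitro_dendritic	culture medium	500	uM	MUTZ-3 dendritic cells, 24 h exposure
Trimellitic anhydride	552-30-7	in_vitro_epithelial	culture medium	2730	uM	16HBE14o epithelial cells, 4 h exposure at 80% viability
Trimellitic anhydride	552-30-7	in_vitro_dendritic	culture medium	150	uM	MUTZ-3 dendritic cells, 24 h exposure
Trimellitic anhydride	552-30-7	in_vivo_predicted	plasma	0.009	uM	generic PBK plasma Cmax, inhalation at low occupational limit, low end
Trimellitic anhydride	552-30-7	in_vivo_predicted	plasma	0.01	uM	generic PBK plasma Cmax, inhalation at low occupational limit, high end
Trimellitic anhydride	552-30-7	in_vivo_predicted	plasma	0.17	uM	generic PBK plasma Cmax, inhalation at higher exposure, low end
Trimellitic anhydride	552-30-7	in_vivo_predicted	plasma	0.19	uM	generic PBK plasma Cmax, inhalation at higher exposure, high end
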