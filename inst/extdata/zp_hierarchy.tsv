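# Two-level trait catalog: 21 general + 27 granular ZP traits, plus the
# special whole-specimen categories (normal, hatched). Ids never published
# carry ZP:UNSPEC_* placeholders; see the provenance column.
granular_curie	general_curie	label	provenance
ZP:0005632	ZP:0005632	abnormal	published summary table
ZP:0127724	ZP:0127724	abnormal axis	published summary table
ZP:0012799	ZP:0012799	abnormal body length	published summary table
ZP:0000100	ZP:0000100	abnormal brain	published summary table
ZP:0000943	ZP:0000943	abnormal eye	published summary table
ZP:0002008	ZP:0002008	abnormal gut	published summary table
ZP:0001609	ZP:0001609	abnormal head	published summary table
ZP:0000107	ZP:0000107	abnormal heart	published summary table
ZP:0007203	ZP:0007203	abnormal jaw	published summary table
ZP:0000624	ZP:0000624	abnormal notochord	published summary table
ZP:0001601	ZP:0001601	abnormal otic vesicle	published summary table
ZP:0001610	ZP:0001610	abnormal pectoral fin	published summary table
ZP:0015121	ZP:0015121	abnormal pigmentation	published summary table
ZP:0014550	ZP:0014550	abnormal snout	published summary table
ZP:0127709	ZP:0127709	abnormal swim bladder	published summary table
ZP:0001129	ZP:0001129	abnormal tail	published summary table
ZP:0003437	ZP:0003437	abnormal trunk	published summary table
ZP:0002676	ZP:0002676	abnormal yolk	published summary table
ZP:0000306	ZP:0000306	dead	published summary table
ZP:0000398	ZP:0000398	necrosis	published summary table
ZP:UNSPEC_G21	ZP:UNSPEC_G21	abnormal somite	named in results text; placeholder id
ZP:UNSPEC_01	ZP:0127724	abnormally curved axis	named in results text; placeholder id
ZP:UNSPEC_02	ZP:0012799	unspecified body length child 1	placeholder (child count only)
ZP:UNSPEC_03	ZP:0000943	abnormally small eye	named in results text; placeholder id
ZP:UNSPEC_04	ZP:0002008	unspecified gut child 1	placeholder (child count only)
ZP:UNSPEC_05	ZP:0001609	abnormally necrotic head	named in results text; placeholder id
ZP:UNSPEC_06	ZP:0001609	abnormally small head	named in results text; placeholder id
ZP:UNSPEC_07	ZP:0001609	hemorrhagic head	named in discussion text; placeholder id
ZP:UNSPEC_08	ZP:0000107	pericardial edema	named in methods text; placeholder id
ZP:UNSPEC_09	ZP:0000107	unspecified heart child 1	placeholder (child count only)
ZP:UNSPEC_10	ZP:0007203	abnormally small jaw	named in results text; placeholder id
ZP:UNSPEC_11	ZP:0007203	abnormally large jaw	named in results text; placeholder id
ZP:UNSPEC_12	ZP:0000624	unspecified notochord child 1	placeholder (child count only)
ZP:UNSPEC_13	ZP:0000624	unspecified notochord child 2	placeholder (child count only)
ZP:UNSPEC_14	ZP:0000624	unspecified notochord child 3	placeholder (child count only)
ZP:UNSPEC_15	ZP:0000624	unspecified notochord child 4	placeholder (child count only)
ZP:UNSPEC_16	ZP:0015121	unspecified pigmentation child 1	placeholder (child count only)
ZP:UNSPEC_17	ZP:0127709	unspecified swim bladder child 1	placeholder (child count only)
ZP:UNSPEC_18	ZP:0127709	unspecified swim bladder child 2	placeholder (child count only)
ZP:UNSPEC_19	ZP:0127709	unspecified swim bladder child 3	placeholder (child count only)
ZP:0004969	ZP:0001129	abnormal tail fin	published mapping table
ZP:0010319	ZP:0001129	abnormally curved tail	published mapping table
ZP:0001130	ZP:0001129	abnormally short tail	published mapping table
ZP:UNSPEC_20	ZP:0002676	yolk sac edema	named in results text; placeholder id
ZP:UNSPEC_21	ZP:0002676	abnormally large yolk	named in results text; placeholder id
ZP:UNSPEC_22	ZP:0002676	unspecified yolk child 1	placeholder (child count only)
ZP:UNSPEC_23	ZP:0002676	unspecified yolk child 2	placeholder (child count only)
ZP:UNSPEC_24	ZP:0002676	unspecified yolk child 3	placeholder (child count only)
normal	normal	normal	whole-specimen category (no CURIE)
hatched	hatched	hatched	whole-specimen category (no CURIE)
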