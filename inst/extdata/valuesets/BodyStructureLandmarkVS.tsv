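display	system	code	synonyms
spleen	sct	78961009	spleen
right kidney	sct	9846003	kidney_right
left kidney	sct	18639004	kidney_left
gallbladder	sct	28231008	gallbladder
liver	sct	10200004	liver
stomach	sct	69695003	stomach
aorta	sct	15825003	aorta
inferior vena cava	sct	64131007	inferior_vena_cava
portal and splenic vein	local	ts-portal-vein-and-splenic-vein	portal_vein_and_splenic_vein
pancreas	sct	15776009	pancreas
right adrenal gland	local	ts-adrenal-gland-right	adrenal_gland_right
left adrenal gland	local	ts-adrenal-gland-left	adrenal_gland_left
left upper lung lobe	local	ts-lung-upper-lobe-left	lung_upper_lobe_left
left lower lung lobe	local	ts-lung-lower-lobe-left	lung_lower_lobe_left
right upper lung lobe	local	ts-lung-upper-lobe-right	lung_upper_lobe_right
right middle lung lobe	local	ts-lung-middle-lobe-right	lung_middle_lobe_right
right lower lung lobe	local	ts-lung-lower-lobe-right	lung_lower_lobe_right
vertebra L5	local	ts-vertebrae-L5	vertebrae_L5
vertebra L4	local	ts-vertebrae-L4	vertebrae_L4
vertebra L3	local	ts-vertebrae-L3	vertebrae_L3
vertebra L2	local	ts-vertebrae-L2	vertebrae_L2
vertebra L1	local	ts-vertebrae-L1	vertebrae_L1
vertebra T12	local	ts-vertebrae-T12	vertebrae_T12
vertebra T11	local	ts-vertebrae-T11	vertebrae_T11
vertebra T10	local	ts-vertebrae-T10	vertebrae_T10
vertebra T9	local	ts-vertebrae-T9	vertebrae_T9
vertebra T8	local	ts-vertebrae-T8	vertebrae_T8
vertebra T7	local	ts-vertebrae-T7	vertebrae_T7
vertebra T6	local	ts-vertebrae-T6	vertebrae_T6
vertebra T5	local	ts-vertebrae-T5	vertebrae_T5
vertebra T4	local	ts-vertebrae-T4	vertebrae_T4
vertebra T3	local	ts-vertebrae-T3	vertebrae_T3
vertebra T2	local	ts-vertebrae-T2	vertebrae_T2
vertebra T1	local	ts-vertebrae-T1	vertebrae_T1
vertebra C7	local	ts-vertebrae-C7	vertebrae_C7
vertebra C6	local	ts-vertebrae-C6	vertebrae_C6
vertebra C5	local	ts-vertebrae-C5	vertebrae_C5
vertebra C4	local	ts-vertebrae-C4	vertebrae_C4
vertebra C3	local	ts-vertebrae-C3	vertebrae_C3
vertebra C2	local	ts-vertebrae-C2	vertebrae_C2
vertebra C1	local	ts-vertebrae-C1	vertebrae_C1
esophagus	sct	32849002	esophagus
trachea	sct	44567001	trachea
heart myocardium	sct	74281007	heart_myocardium
left cardiac atrium	local	ts-heart-atrium-left	heart_atrium_left
left cardiac ventricle	local	ts-heart-ventricle-left	heart_ventricle_left
right cardiac atrium	local	ts-heart-atrium-right	heart_atrium_right
right cardiac ventricle	local	ts-heart-ventricle-right	heart_ventricle_right
pulmonary artery	sct	81040000	pulmonary_artery
brain	sct	12738006	brain
left iliac artery	local	ts-iliac-artery-left	iliac_artery_left
right iliac artery	local	ts-iliac-artery-right	iliac_artery_right
left iliac vein	local	ts-iliac-vena-left	iliac_vena_left
right iliac vein	local	ts-iliac-vena-right	iliac_vena_right
small bowel	sct	30315005	small_bowel
duodenum	sct	38848004	duodenum
colon	sct	71854001	colon
left rib 1	local	ts-rib-left-1	rib_left_1
left rib 2	local	ts-rib-left-2	rib_left_2
left rib 3	local	ts-rib-left-3	rib_left_3
left rib 4	local	ts-rib-left-4	rib_left_4
left rib 5	local	ts-rib-left-5	rib_left_5
left rib 6	local	ts-rib-left-6	rib_left_6
left rib 7	local	ts-rib-left-7	rib_left_7
left rib 8	local	ts-rib-left-8	rib_left_8
left rib 9	local	ts-rib-left-9	rib_left_9
left rib 10	local	ts-rib-left-10	rib_left_10
left rib 11	local	ts-rib-left-11	rib_left_11
left rib 12	local	ts-rib-left-12	rib_left_12
right rib 1	local	ts-rib-right-1	rib_right_1
right rib 2	local	ts-rib-right-2	rib_right_2
right rib 3	local	ts-rib-right-3	rib_right_3
right rib 4	local	ts-rib-right-4	rib_right_4
right rib 5	local	ts-rib-right-5	rib_right_5
right rib 6	local	ts-rib-right-6	rib_right_6
right rib 7	local	ts-rib-right-7	rib_right_7
right rib 8	local	ts-rib-right-8	rib_right_8
right rib 9	local	ts-rib-right-9	rib_right_9
right rib 10	local	ts-rib-right-10	rib_right_10
right rib 11	local	ts-rib-right-11	rib_right_11
right rib 12	local	ts-rib-right-12	rib_right_12
left humerus	local	ts-humerus-left	humerus_left
right humerus	local	ts-humerus-right	humerus_right
left scapula	local	ts-scapula-left	scapula_left
right scapula	local	ts-scapula-right	scapula_right
left clavicle	local	ts-clavicula-left	clavicula_left
right clavicle	local	ts-clavicula-right	clavicula_right
left femur	local	ts-femur-left	femur_left
right femur	local	ts-femur-right	femur_right
left hip	local	ts-hip-left	hip_left
right hip	local	ts-hip-right	hip_right
sacrum	sct	54735007	sacrum
face	local	ts-face	face
left gluteus maximus	local	ts-gluteus-maximus-left	gluteus_maximus_left
right gluteus maximus	local	ts-gluteus-maximus-right	gluteus_maximus_right
left gluteus medius	local	ts-gluteus-medius-left	gluteus_medius_left
right gluteus medius	local	ts-gluteus-medius-right	gluteus_medius_right
left gluteus minimus	local	ts-gluteus-minimus-left	gluteus_minimus_left
right gluteus minimus	local	ts-gluteus-minimus-right	gluteus_minimus_right
left autochthonous back muscle	local	ts-autochthon-left	autochthon_left
right autochthonous back muscle	local	ts-autochthon-right	autochthon_right
left iliopsoas	local	ts-iliopsoas-left	iliopsoas_left
right iliopsoas	local	ts-iliopsoas-right	iliopsoas_right
urinary bladder	sct	89837001	urinary_bladder
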