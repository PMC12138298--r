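display	system	code	synonyms
whole body	sct	38266002	entire body
abdominal cavity	sct	52731004	
thoracic cavity	sct	43799004	
mediastinum	sct	72410000	
pericardium	sct	76848001	
pelvic cavity	local	bca-pelvic-cavity	
retroperitoneum	local	bca-retroperitoneum	
extremities	local	bca-extremities	
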