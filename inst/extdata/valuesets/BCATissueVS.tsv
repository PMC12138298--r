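display	system	code	synonyms
muscle	local	bca-muscle	skeletal muscle
bone	local	bca-bone	
subcutaneous adipose tissue	local	bca-sat	SAT
visceral adipose tissue	local	bca-vat	VAT
intramuscular adipose tissue	local	bca-imat	IMAT
intermuscular adipose tissue	local	bca-immat	
epicardial adipose tissue	local	bca-eat	EAT
paracardial adipose tissue	local	bca-pat	PAT
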