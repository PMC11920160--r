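drug_name	atc_code
Clozapine	N05AH02
Olanzapine	N05AH03
Ibuprofen	M01AE01
Metformin	A10BA02
Methotrexate	L01BA01
Amoxicillin	J01CA04
Azithromycin	J01FA10
Furosemide	C03CA01
Thiamazole	H03BB02
Deferiprone	V03AC02
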