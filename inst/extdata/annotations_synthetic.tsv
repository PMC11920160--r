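drug	agran_documented	hematologic_documented	case_report
Clozapine	TRUE	TRUE	TRUE
Olanzapine	TRUE	TRUE	FALSE
Ibuprofen	TRUE	TRUE	FALSE
Metformin	FALSE	FALSE	TRUE
Amoxicillin	TRUE	TRUE	FALSE
Azithromycin	FALSE	TRUE	TRUE
Furosemide	FALSE	TRUE	FALSE
Thiamazole	TRUE	TRUE	FALSE
Deferiprone	TRUE	TRUE	FALSE
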