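label	deaths	non_deaths
2004-2010	262	1937
2011-2015	245	2111
2016-2020	361	3414
2021-2024	188	2395
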