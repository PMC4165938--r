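>plectasin family=fDEF1
GFGCNGPWDEDDMQCHNHCKSIKGYKGGYCAKGGFVCKCY
>anchor_fDEF1_synthetic family=fDEF1
GFGCNGPDVEDDLQCHNHCKSIKGYKGGACAKRGDVCQCY
>anchor_fDEF2_synthetic family=fDEF2
ATYCPSDPWGNNLACFGHCRTFGGVGLGYCSNHFTCNCKA
>anchor_fDEF3_synthetic family=fDEF3
QVCAGSNDAAQCIAHCYTSGGYRGGYCIQTYMCTCVG
>anchor_fDEF4_synthetic family=fDEF4
STHACLSGGIMNATSCTWWCASPFNIGHAQCANLHGCECNH
>anchor_fDEF6_synthetic family=fDEF6
NHCIKGPRIDALTCKDHCGKNYKGRYGGCKGGFKCKCGK
>anchor_fDEF8_synthetic family=fDEF8
EQCFKGWDDELLACNGHCYSMIVGYMGGCQHNDGCKCHRPG
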