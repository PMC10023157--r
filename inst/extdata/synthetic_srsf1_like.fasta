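>SYN_SRSF1_LIKE synthetic stand-in sequence; planted maximal RS runs of 16, 6 and 5
PVICINPHDQVPMKTCAWNGLNPIVQIKLGEINFDDFIWTMWALQDHMQVMIMDHAQANP
THQVDKFYMMNCGGMAKKEYQITHNVWHAWSRMCVAMANTCLYCTKKNLFMAYWCYVPNH
PVLPLATTDDAEHCQHTHKYVFLDDKQAGDFGQKVDVAAYAHWDYNQARSRSRSRSRSRS
RSRSVGKCKRSRNNVASRSRSRLYMTPTFERSRSRTLQKEGALMNCDCKF
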