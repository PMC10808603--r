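subject_id,hr_segmentation,hr_oximeter
Subject 01,73,73
Subject 02,74,73
Subject 03,73,73
Subject 04,72,72
Subject 05,73,73
Subject 06,72,73
Subject 07,73,73
Subject 08,73,73
Subject 09,73,73
Subject 10,73,73
Subject 11,73,73
Subject 12,71,72
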