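ID,Nephro 1,Nephro 2,Nephro 3,App
1,Low risk,Low risk,Low risk,Low risk
2,High risk,Moderate risk,High risk,Moderate risk
3,High risk,Moderate risk,High risk,Moderate risk
4,Low risk,Moderate risk,High risk,Low risk
5,Low risk,Low risk,Low risk,Low risk
6,Very high risk,Very high risk,High risk,Very high risk
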