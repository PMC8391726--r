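word	degree
存在	3.42
概念	3.38
意識	3.21
関係	3.15
状態	3.08
気持ち	2.95
時間	2.91
世界	2.88
未来	2.84
自由	2.81
心	2.76
夢	2.71
言葉	2.64
物語	2.58
音楽	2.43
学校	2.21
友達	2.14
家族	2.09
部屋	1.92
手紙	1.85
街	1.78
森	1.66
海	1.62
山	1.58
花	1.45
犬	1.31
猫	1.28
本	1.52
机	1.24
雨	1.49
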