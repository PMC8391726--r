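word	sadness	anxiety	anger	disgust	trust	surprise	happiness
嬉しい	0	0	0	0	0.1	0.1	0.8
悲しい	0.8	0.1	0	0.1	0	0	0
寂しい	0.7	0.2	0	0	0	0	0.1
怒る	0	0.1	0.8	0.1	0	0	0
憤り	0	0	0.9	0.1	0	0	0
嫌い	0	0	0.2	0.8	0	0	0
不安	0.1	0.8	0	0	0	0.1	0
恐れ	0.1	0.7	0	0.1	0	0.1	0
信じる	0	0	0	0	0.9	0	0.1
安心	0	0.1	0	0	0.7	0	0.2
驚く	0	0.1	0	0	0	0.8	0.1
びっくり	0	0.2	0	0	0	0.7	0.1
幸せ	0	0	0	0	0.2	0	0.8
楽しい	0	0	0	0	0.1	0.1	0.8
喜ぶ	0	0	0	0	0.1	0.2	0.7
笑う	0	0	0	0	0.1	0.2	0.7
泣く	0.7	0.1	0	0	0	0.2	0
涙	0.6	0.2	0	0	0	0.1	0.1
絶望	0.6	0.3	0	0.1	0	0	0
憂鬱	0.5	0.4	0	0.1	0	0	0
苛立ち	0	0.2	0.7	0.1	0	0	0
軽蔑	0	0	0.3	0.7	0	0	0
うんざり	0.1	0	0.2	0.7	0	0	0
頼る	0	0.1	0	0	0.8	0	0.1
仲間	0	0	0	0	0.6	0	0.4
裏切り	0.2	0.1	0.4	0.3	0	0	0
衝撃	0	0.3	0	0	0	0.7	0
意外	0	0.1	0	0	0	0.8	0.1
感動	0	0	0	0	0.1	0.3	0.6
希望	0	0.1	0	0	0.3	0	0.6
夢	0	0.1	0	0	0.2	0.1	0.6
恋	0.1	0.2	0	0	0.1	0.1	0.5
愛	0	0	0	0	0.4	0	0.6
孤独	0.7	0.2	0	0.1	0	0	0
後悔	0.5	0.3	0.1	0.1	0	0	0
焦り	0.1	0.7	0.1	0.1	0	0	0
憎む	0.1	0	0.5	0.4	0	0	0
呆れる	0	0	0.2	0.5	0	0.3	0
祝う	0	0	0	0	0.2	0.1	0.7
微笑む	0	0	0	0	0.3	0	0.7
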