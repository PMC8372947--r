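group	state	count
1	loss	10
1	gain	8
1	hemizygous_loss	1
2	loss	5
2	gain	8
3	loss	7
3	gain	12
3	homozygous_loss	4
3	hemizygous_loss	1
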