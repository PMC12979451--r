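group,female,male
MDD-CM,67,17
MDD-nCM,28,18
HC-CM,21,11
HC-nCM,58,32
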