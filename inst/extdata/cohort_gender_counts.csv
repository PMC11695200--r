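group,female,male
case,31,35
control,32,22
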