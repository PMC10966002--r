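sex,cases
men,304916
women,337097
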