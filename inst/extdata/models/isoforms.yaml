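# Isoform hierarchy: specific isoform -> general protein class.
PKCTHETA: NPKC
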