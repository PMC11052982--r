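Now extract the entities from the input text above and respond in the specified format.
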