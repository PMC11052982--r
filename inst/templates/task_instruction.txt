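Identify every rare disease, disease, symptom, and sign entity mentioned in the input text, and extract their exact names verbatim from the text without rephrasing, abbreviating, or normalizing them.
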