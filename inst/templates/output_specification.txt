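Report the extracted entities as one line per entity type, each a comma-separated list, in exactly this format: "rare disease: <name>, <name>, ..." then "disease: ...", "symptom: ...", and "sign: ..."; if the text contains no entities of a type, write none for that type.
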