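rare_disease	Diseases which affect a small number of people compared to the general population.
disease	An abnormal condition of a part, organ, or system of an organism resulting from various causes, such as infection, inflammation, environmental factors, or genetic defect, and characterized by an identifiable group of signs, symptoms, or both.
symptom	A physical or mental problem that may indicate a disease or condition; cannot be seen and does not show up on medical tests.
sign	A physical or mental problem that may indicate a disease or condition; can be seen and shows up on medical tests.
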