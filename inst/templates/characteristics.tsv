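rare_disease	Rare diseases often come with terms like "rare", "uncommon", or mentions of specific low-prevalence numbers. For example, in the sentence, "Ablepharon-Macrostomia Syndrome (AMS) is an extremely rare inherited disorder," "Ablepharon-Macrostomia Syndrome" and "AMS" are rare diseases, but "inherited disorder" is not.
disease	Diseases are generally recognized medical conditions. The mention of a disease might not necessarily come with descriptors of its prevalence unless it's rare. For example, in the sentence, "Ablepharon-Macrostomia Syndrome (AMS) is an extremely rare inherited disorder," "inherited disorder" is a disease.
symptom	Symptoms are subjective and detected by the patient. For example, in the sentence, "In the acute form, drowsiness, coma, and seizures may occur," "drowsiness" is a symptom, but "coma" and "seizures" are not.
sign	Signs can be measured or observed and don't rely on the patient's subjective reporting. For example, in the sentence, "In the acute form, drowsiness, coma, and seizures may occur," "coma" and "seizures" are signs, but "drowsiness" is not.
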