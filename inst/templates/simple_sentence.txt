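{task_instruction} In the input text, {task_guidance} {output_specification}{example_block}

Input text: {target_text}

{output_retrieval}
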