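1. Task instruction: {task_instruction}
2. Task guidance:
{task_guidance}
3. Output specification: {output_specification}{example_block}
4. Input text: {target_text}
5. Output retrieval: {output_retrieval}
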