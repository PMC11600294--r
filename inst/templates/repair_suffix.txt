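

<<PREVIOUS_ATTEMPT>>
Your previous code for this task was:
{{previous_code}}
Executing it produced the following error output:
{{error_excerpt}}
<</PREVIOUS_ATTEMPT>>

Fix the code so it executes without errors. Respond again with exactly one
fenced shell code block containing the complete corrected script.
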