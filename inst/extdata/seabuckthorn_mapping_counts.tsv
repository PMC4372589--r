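metric	count
reference_tags_mapped	234300
unambiguous	225643
ambiguous	8657
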