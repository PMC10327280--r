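subject_id: subject_id
cohort: cohort
diagnosis: diagnosis
sex: sex
age: age
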