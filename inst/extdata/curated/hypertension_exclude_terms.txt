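early-onset hypertension
pulmonary arterial hypertension
pseudotumor cerebri
treatment-resistant hypertension
preeclampsia
chemotherapy-induced hypertension
short sleep duration
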