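report_id	drugs	events	outcomes	roles	period
R1	D1|D2	E1
R2	D1|D2	E1
R3	D1	E2
R4	D2	E1
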