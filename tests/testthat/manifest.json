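{"command":"validate-config","flags":{"config":"/root/pkg/inst/extdata/drugs/diclofenac.yaml"},"seed":1,"package_version":"0.1.0","timestamp":"2026-09-22T21:01:50+0000","outputs":[]}
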