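id,name,ka_per_M_s,kd_per_s,KD_M
1,1-DIQMAQ,1.1e5,2.9e-4,2.6e-9
2,2-DIQMAQ-K,1.3e5,3.8e-4,3.0e-9
3,3-EIVLAQ,2.0e5,3.1e-4,1.5e-9
4,4-DIQMGQ,1.6e5,5.6e-4,4.3e-9
5,5-DIQMAE,1.6e5,4.0e-4,2.5e-9
6,6-EIVLGQ,2.6e5,6.4e-4,2.7e-9
7,7-EIVLAE,1.8e5,4.4e-4,2.4e-9
8,8-DIQMGE,1.3e5,5.4e-4,4.2e-9
9,9-EIVLGE,3.1e5,4.4e-4,1.4e-9
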