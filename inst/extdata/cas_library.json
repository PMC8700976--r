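{"SpCas9":{"name":"SpCas9","pam_patterns":"NGG","pam_side":"downstream","window":[4,8],"compatible_editors":["ABE","CBE","GBE"],"protospacer_len":20,"size_aa":1368},"xCas/SpCas9-NG":{"name":"xCas/SpCas9-NG","pam_patterns":"NG","pam_side":"downstream","window":[4,8],"compatible_editors":["ABE","CBE","GBE"],"protospacer_len":20,"size_aa":null},"SaCas9":{"name":"SaCas9","pam_patterns":"NNGRRT","pam_side":"downstream","window":[4,12],"compatible_editors":["ABE","CBE"],"protospacer_len":20,"size_aa":1053},"SaCas9-KKH":{"name":"SaCas9-KKH","pam_patterns":"NNNRRT","pam_side":"downstream","window":[2,15],"compatible_editors":["ABE","CBE"],"protospacer_len":20,"size_aa":null},"LbCas12a":{"name":"LbCas12a","pam_patterns":"TTTV","pam_side":"upstream","window":[8,13],"compatible_editors":["ABE","CBE"],"protospacer_len":20,"size_aa":1228},"enAsCas12a":{"name":"enAsCas12a","pam_patterns":["TATV","TYCV"],"pam_side":"upstream","window":[8,13],"compatible_editors":["ABE","CBE"],"protospacer_len":20,"size_aa":null},"CasMINI":{"name":"CasMINI","pam_patterns":"TTTV","pam_side":"upstream","window":[3,4],"compatible_editors":"ABE","protospacer_len":20,"size_aa":529}}
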