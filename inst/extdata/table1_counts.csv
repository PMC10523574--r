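target,dataset,total,inactive,active
AChM1R,internal_train,3811,2829,982
AChM1R,internal_test,876,745,131
AChM1R,sohn_federated,20000,10000,10000
AChM1R,mlp_federated,20000,10000,10000
AChM1R,public,2191,1288,903
GABA_A,internal_train,3614,3216,398
GABA_A,internal_test,877,819,58
GABA_A,sohn_federated,20000,10000,10000
GABA_A,mlp_federated,20000,14915,5085
GABA_A,public,2433,1645,788
5-HT2B,internal_train,3374,2447,927
5-HT2B,internal_test,876,709,167
5-HT2B,sohn_federated,20000,10000,10000
5-HT2B,mlp_federated,20000,10000,10000
5-HT2B,public,1506,685,821
hERG,internal_train,2285,1388,897
hERG,internal_test,556,309,247
hERG,sohn_federated,20000,10000,10000
hERG,mlp_federated,20000,10000,10000
hERG,public,8298,4157,4141
COX2,internal_train,3042,2815,227
COX2,internal_test,881,809,72
COX2,sohn_federated,20000,12233,7767
COX2,mlp_federated,20000,10535,9465
COX2,public,3228,1545,1683
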