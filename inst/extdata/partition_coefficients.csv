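composition,calcium,variant,K,K_err
7% PtdSer,with_Ca,WT,1.0e3,0.1e3
7% PtdSer,with_Ca,K326A,3.4e2,0.4e2
2% PtdInsP2,with_Ca,WT,2.2e4,0.2e4
2% PtdInsP2,with_Ca,K326A,5.1e3,0.5e3
2% PtdInsP2,with_Ca,KAKA,1.1e3,0.1e3
5% PtdSer + 0.5% PtdInsP2,with_Ca,WT,5.0e4,0.7e4
5% PtdSer + 0.5% PtdInsP2,with_Ca,K326A,2.2e4,0.3e4
5% PtdSer + 0.5% PtdInsP2,with_Ca,KAKA,1.0e4,0.1e4
25% PtdSer,no_Ca,WT,2.7e2,0.3e2
2% PtdInsP2,no_Ca,WT,1.1e3,0.2e3
10% PtdSer + 2% PtdInsP2,no_Ca,WT,4.7e4,0.9e4
10% PtdSer + 2% PtdInsP2,no_Ca,KAKA,2.7e2,0.3e2
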