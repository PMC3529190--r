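model,term,type,beta
bcddp,agecat,main,0.01081
bcddp,agemen,main,0.09401
bcddp,ageflb,main,0.21863
bcddp,numrel,main,0.9583
bcddp,nbiops,main,0.52926
bcddp,atypical,main,0.57405
bcddp,nbiopsxagecat,interaction,-0.28804
bcddp,ageflbxnumrel,interaction,-0.19081
bcddp,ar_under50,attributable-risk,0.4771
bcddp,ar_50plus,attributable-risk,0.4736
gail-sbsp,agecat,main,0.01081
gail-sbsp,agemen,main,0.09401
gail-sbsp,ageflb,main,0.21863
gail-sbsp,numrel,main,0.9583
gail-sbsp,nbiops,main,0.52926
gail-sbsp,nbiopsxagecat,interaction,-0.28804
gail-sbsp,ageflbxnumrel,interaction,-0.19081
gail-sbsp,ar_under50,attributable-risk,0.4771
gail-sbsp,ar_50plus,attributable-risk,0.4736
s-gail-sbsp,agemen,main,0.238
s-gail-sbsp,ageflb,main,0.183
s-gail-sbsp,numrel,main,0.777
s-gail-sbsp,ar_under50,attributable-risk,0.4771
s-gail-sbsp,ar_50plus,attributable-risk,0.4736
e-gail-sbsp,agemen,main,0.204
e-gail-sbsp,ageflb,main,0.17
e-gail-sbsp,numrel,main,0.774
e-gail-sbsp,bmi,main,0.38
e-gail-sbsp,parity,main,0.203
e-gail-sbsp,ar_under50,attributable-risk,0.5356
e-gail-sbsp,ar_50plus,attributable-risk,0.5397
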