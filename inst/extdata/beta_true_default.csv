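origin,destination,term,value
s1,s2,intercept,-3.5
s1,s2,age,0.1
s1,s2,oa,0.3
s1,s3,intercept,-3.5
s1,s3,age,0.05
s1,s3,oa,0.7
s1,s4,intercept,-5
s1,s4,age,0.07
s1,s4,oa,0.7
s1,dead,intercept,-6.4
s1,dead,age,0.092
s1,dead,oa,0.1
s2,s1,intercept,-2.5
s2,s1,age,-0.12
s2,s1,oa,-0.3
s2,s3,intercept,-5
s2,s3,age,0
s2,s3,oa,0
s2,s4,intercept,-3.2
s2,s4,age,0.06
s2,s4,oa,0.7
s2,dead,intercept,-6.4
s2,dead,age,0.092
s2,dead,oa,0.1
s3,s1,intercept,-1.5
s3,s1,age,-0.03
s3,s1,oa,-0.5
s3,s2,intercept,-5
s3,s2,age,0
s3,s2,oa,0
s3,s4,intercept,-2.5
s3,s4,age,0.08
s3,s4,oa,0.3
s3,dead,intercept,-5.9
s3,dead,age,0.092
s3,dead,oa,0.1
s4,s1,intercept,-5
s4,s1,age,0
s4,s1,oa,0
s4,s2,intercept,-2
s4,s2,age,-0.05
s4,s2,oa,-0.5
s4,s3,intercept,-3
s4,s3,age,-0.05
s4,s3,oa,-0.3
s4,dead,intercept,-5.1
s4,dead,age,0.092
s4,dead,oa,0.1
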