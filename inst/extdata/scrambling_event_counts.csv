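homolog,structure,in_groove,out_groove,total,rate_mean,rate_sd
nhTMEM16,4WIS,219,1,220,24.4,5.2
nhTMEM16,6QM6,141,0,141,15.7,3.9
afTMEM16,7RXG,96,0,96,10.7,2.9
TMEM16K,5OC9,66,8,74,8.2,2.9
TMEM16K,6R7X,0,4,4,0.4,0.7
TMEM16F F518H,8B8J,98,4,102,11.3,4.1
TMEM16F,6QP6*,24,3,27,3.0,1.6
TMEM16F T137Y,8TAG,0,9,9,1.0,0.7
TMEM16F,6P47,1,3,4,0.4,0.5
TMEM16F,6P48,0,4,4,0.4,0.5
TMEM16F F518H/Q623A,8BC0,0,4,4,0.4,0.5
TMEM16F F518H,8B8Q,0,4,4,0.4,0.7
TMEM16F F518H,8B8G,2,0,2,0.2,0.4
TMEM16F,6QPB,0,3,3,0.3,0.7
TMEM16A,7ZK3*6,0,11,11,1.2,1.6
TMEM16A,5OYB*,2,0,2,0.2,0.4
TMEM16A,7ZK3*10,0,1,1,0.1,0.3
TMEM16A,7ZK3*8,0,1,1,0.1,0.3
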