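# Replication design for a linear-growth trial with yearly measurements:
# antisocial-behavior tolerance, five equally spaced occasions.
eta: 0.8
BFthres: 3
eff.size: 0.40
m: 1000
t.points: [0, 1, 2, 3, 4]
beta1: 0
log: false
var.u0: 0.0333
var.u1: 0.0030
var.e: 0.0262
cov: 0
fraction: 1
sensitivity: true
hyp: both
test: alt
seed: 1
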