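# Replication design for a log-linear-growth psychotherapy feedback trial
# with irregular occasions (weeks 0, 5, 13, 638). The expected interaction
# is negative (faster improvement under treatment, lower scores = better),
# so the run should use direction = "negative". Time 0 under log growth
# requires the unit shift.
eta: 0.7
BFthres: 10
eff.size: 0.564
m: 1000
t.points: [0, 5, 13, 638]
log: true
log.shift: 1
var.u0: 237.114
var.u1: 13.234
var.e: 172.191
cov: 18.282
fraction: 1
sensitivity: false
hyp: H1
test: Hc
seed: 1
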