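# Verbal associations accepted as relation triggers (one per line).
induce
induces
induced
increase
increases
increased
decrease
decreases
decreased
reduce
reduces
reduced
elevate
elevates
elevated
raise
raises
raised
stimulate
stimulates
stimulated
activate
activates
activated
inhibit
inhibits
inhibited
suppress
suppresses
suppressed
upregulate
upregulates
upregulated
up-regulated
downregulate
downregulates
downregulated
down-regulated
enhance
enhances
enhanced
trigger
triggers
triggered
promote
promotes
promoted
release
releases
released
secrete
secretes
secreted
produce
produces
produced
correlate
correlates
correlated
associated
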