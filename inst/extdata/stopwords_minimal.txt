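# minimal tier: articles + conversational fillers / backchannel particles
a
an
the
uh
um
er
erm
hm
hmm
mm
mhm
mmhm
huh
oh
ah
eh
yeah
yep
yes
no
okay
ok
well
hey
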