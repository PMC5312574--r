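# Fixed ratio 10: reward every 10 counted licks, 20 s timeout, 5 s cue,
# one-hour session. Mirrors the schedule_spec field names.
family: FR
ratio: 10
timeout_s: 20
cue_s: 5
session_s: 3600
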