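behavior:
- score: 0
  values:
  - playing
  - appropriate
- score: 1
  values: sleeping
- score: 2
  values: irritable
- score: 3
  values:
  - lethargic
  - confused
  - reduced pain response
cardiovascular:
- score: 0
  values:
  - pink
  - crt 1-2s
- score: 1
  values:
  - pale
  - crt 3s
- score: 2
  values:
  - grey
  - crt 4s
- score: 3
  values:
  - grey and mottled
  - crt 5s+
respiratory:
- score: 0
  values:
  - normal
  - no recession
- score: 1
  values:
  - rr high by 10
  - accessory muscles
  - o2 under 4l
- score: 2
  values:
  - rr high by 20
  - recession
  - o2 over 4l
- score: 3
  values:
  - rr low below normal
  - grunting
  - o2 over 8l
version: synthetic-1.0
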