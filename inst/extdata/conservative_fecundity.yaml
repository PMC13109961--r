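# Alternative preset: conservative egg-to-recruit conversion. Identical to
# the defaults except for the effective fecundities.
assemblages:
  fast_reef:     {f: 4.0e-4}
  slow_reef:     {f: 5.0e-3}
  fast_nonreef:  {f: 4.0e-4}
  slow_nonreef:  {f: 5.0e-3}
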