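# Default model configuration: the standard four-assemblage
# parameterization, written out in full. Loading this file is equivalent to
# loading an empty config; edit a copy to run perturbed configurations.
assemblages:
  fast_reef:
    s0: 0.05       # max linear extension rate, m/yr
    w: 6           # thermal tolerance breadth, degC
    wH: 0.5        # heat stress tolerance, degC
    zH: 1.5        # heat stress threshold above z, degC
    wC: 0.75       # cold stress tolerance, degC
    zC: 8          # cold stress threshold below z, degC
    wA: 6          # absolute-limit tolerance, degC
    zA: 24.2       # absolute lower thermal limit, degC
    V: 0.05        # additive genetic variance, degC^2
    f: 0.008       # effective fecundity
    r_pH: 0.5      # extension-rate sensitivity per pH unit
    pH0: 8.1       # reference pH
    R_sat: 15      # saturation PAR, mol m-2 day-1
    mu: -4.2       # log-normal colony-size meanlog
    sigma: 1.9     # log-normal colony-size sdlog
    mN: 0          # natural mortality, 1/yr
    kernel_id: AM
  slow_reef:
    s0: 0.01
    w: 6
    wH: 1.0
    zH: 1.5
    wC: 1.5
    zC: 8
    wA: 6
    zA: 21.3
    V: 0.05
    f: 0.1
    kernel_id: GR
  fast_nonreef:
    s0: 0.05
    w: 8
    wH: 0.5
    zH: 3.5
    wC: 0.75
    zC: 10
    wA: 8
    zA: 22.9
    V: 0.05
    f: 0.008
    kernel_id: AM
  slow_nonreef:
    s0: 0.01
    w: 8
    wH: 1.0
    zH: 3.5
    wC: 1.5
    zC: 10
    wA: 8
    zA: 19.1
    V: 0.05
    f: 0.1
    kernel_id: GR
competition:
  reef_reef: 2
  nonreef_nonreef: 10
  reef_nonreef: 1.2
  nonreef_reef: 0.8
global:
  C_min: 1.0e-9
  C_throttle: 1.0e-3
  substeps: 4
  seed: 1
  output_every: 12
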