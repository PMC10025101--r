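# Example model configuration: all keys optional; omitted keys fall back to
# the reference defaults (see ?urchin_model).
delta_rho: 30      # acceptance angle (deg)
delta: 15          # half-width of photoreceptor band (deg)
theta_p: 5         # population-vector detection threshold
a_rr: 0.25         # lateral strength, radial nerves
a_oo: 0.25         # lateral strength, oral nerve ring
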