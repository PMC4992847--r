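# Shared fixtures: reference parameter sets from the built-in registry.
pwl2 <- neuron_model("pwl2d")
pwl3 <- neuron_model("pwl3d")
qif <- neuron_model("qif")
fhn <- neuron_model("fhn")
bfhn <- neuron_model("boltzmann-fhn")
hh <- neuron_model("hh")

# settled HH rest, reused across tests (deterministic)
hh_rest <- settle_rest(hh)

# frozen reference constants, derived once from the eigen-decomposition of
# the middle-region Jacobian [[0.5, -1], [0.09, -0.2]] and the intercept
# formula b_theta = (i_e + b_m)(k_w - k_theta)/(k_w - k_m)
K_THETA <- 0.5 + (sqrt(0.13) - 0.3) / 2     # 0.530277563773...
B_THETA <- (-1.5) * (0.45 - K_THETA) / (0.45 - 0.5)
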