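# Growth calibration for the high-water compartment of the
# resource-partitioned treatment: fewer but longer primaries with a wider
# branching interval and progressively suppressed branching numbers >= 2.
[calibration]
name = "water"
max_order = 4

[order0]
r_mean = 1.05
r_sd = 0.09
lmax_mean = 13.0
lmax_sd = 2.0
la = 0.8
lb = 0.7
ln_mean = 0.2457
ln_sd = 0.025
theta_mean = 15.0
theta_sd = 8.0
maxB = 8
radius = 0.035
linear_density = 0.0008088
tropism_sigma = 6.0

[order1]
r_mean = 0.35
r_sd = 0.05
lmax_mean = 0.65
lmax_sd = 0.20
la = 0.33
lb = 0.32
ln_mean = 0.65
ln_sd = 0.10
theta_mean = 53.0
theta_sd = 8.0
radius = 0.015
linear_density = 0.00013143
tropism_sigma = 15.0

[order2]
r_mean = 0.05
r_sd = 0.01
lmax_mean = 0.22
lmax_sd = 0.08
la = 0.11
lb = 0.11
ln_mean = 0.25
ln_sd = 0.05
theta_mean = 59.3
theta_sd = 8.0
radius = 0.010
linear_density = 0.0001011
tropism_sigma = 15.0

[order3]
r_mean = 0.012
r_sd = 0.004
lmax_mean = 0.10
lmax_sd = 0.04
la = 0.05
lb = 0.05
ln_mean = 0.25
ln_sd = 0.05
theta_mean = 60.9
theta_sd = 8.0
radius = 0.008
linear_density = 8.088e-05
tropism_sigma = 15.0

[order4]
r_mean = 0.008
r_sd = 0.003
lmax_mean = 0.06
lmax_sd = 0.02
la = 0.03
lb = 0.03
ln_mean = 1.0
ln_sd = 0.0
theta_mean = 62.3
theta_sd = 8.0
radius = 0.008
linear_density = 6.066e-05
tropism_sigma = 15.0
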