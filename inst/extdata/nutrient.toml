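# Growth calibration for the nutrient compartment of the resource-partitioned
# treatment: shorter primaries, dense lateral branching down to branching
# number 4. Reverse-engineered from published per-order trait summaries.
[calibration]
name = "nutrient"
max_order = 4

[order0]
r_mean = 1.1
r_sd = 0.1
lmax_mean = 9.0
lmax_sd = 1.5
la = 0.6
lb = 0.4
ln_mean = 0.19
ln_sd = 0.02
theta_mean = 15.0
theta_sd = 8.0
maxB = 6
radius = 0.030
linear_density = 0.0009567
tropism_sigma = 8.0

[order1]
r_mean = 0.45
r_sd = 0.05
lmax_mean = 1.0
lmax_sd = 0.3
la = 0.45
lb = 0.35
ln_mean = 0.45
ln_sd = 0.08
theta_mean = 48.2
theta_sd = 8.0
radius = 0.015
linear_density = 0.00023386
tropism_sigma = 15.0

[order2]
r_mean = 0.2
r_sd = 0.04
lmax_mean = 0.45
lmax_sd = 0.18
la = 0.23
lb = 0.22
ln_mean = 0.45
ln_sd = 0.09
theta_mean = 55.5
theta_sd = 8.0
radius = 0.010
linear_density = 0.00012756
tropism_sigma = 15.0

[order3]
r_mean = 0.15
r_sd = 0.03
lmax_mean = 0.33
lmax_sd = 0.13
la = 0.17
lb = 0.16
ln_mean = 0.33
ln_sd = 0.07
theta_mean = 60.8
theta_sd = 8.0
radius = 0.008
linear_density = 8.504e-05
tropism_sigma = 15.0

[order4]
r_mean = 0.1
r_sd = 0.03
lmax_mean = 0.3
lmax_sd = 0.12
la = 0.15
lb = 0.15
ln_mean = 1.0
ln_sd = 0.0
theta_mean = 61.8
theta_sd = 8.0
radius = 0.008
linear_density = 6.378e-05
tropism_sigma = 15.0
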