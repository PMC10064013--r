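# Growth calibration used for BOTH compartments of the resource-mixed
# treatment (symmetric resource supply): intermediate between the nutrient
# and water calibrations.
[calibration]
name = "mixed"
max_order = 4

[order0]
r_mean = 1.2
r_sd = 0.1
lmax_mean = 11.0
lmax_sd = 1.8
la = 0.70
lb = 0.55
ln_mean = 0.249
ln_sd = 0.025
theta_mean = 15.0
theta_sd = 8.0
maxB = 7
radius = 0.032
linear_density = 0.00055
tropism_sigma = 7.0

[order1]
r_mean = 0.45
r_sd = 0.05
lmax_mean = 0.67
lmax_sd = 0.20
la = 0.33
lb = 0.33
ln_mean = 0.60
ln_sd = 0.10
theta_mean = 51.5
theta_sd = 8.0
radius = 0.015
linear_density = 0.000102
tropism_sigma = 15.0

[order2]
r_mean = 0.08
r_sd = 0.02
lmax_mean = 0.30
lmax_sd = 0.10
la = 0.15
lb = 0.15
ln_mean = 0.30
ln_sd = 0.06
theta_mean = 55.4
theta_sd = 8.0
radius = 0.010
linear_density = 7.8e-05
tropism_sigma = 15.0

[order3]
r_mean = 0.03
r_sd = 0.01
lmax_mean = 0.20
lmax_sd = 0.08
la = 0.10
lb = 0.10
ln_mean = 0.25
ln_sd = 0.05
theta_mean = 65.3
theta_sd = 8.0
radius = 0.008
linear_density = 6.3e-05
tropism_sigma = 15.0

[order4]
r_mean = 0.02
r_sd = 0.008
lmax_mean = 0.10
lmax_sd = 0.04
la = 0.05
lb = 0.05
ln_mean = 1.0
ln_sd = 0.0
theta_mean = 61.4
theta_sd = 8.0
radius = 0.008
linear_density = 5.5e-05
tropism_sigma = 15.0
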