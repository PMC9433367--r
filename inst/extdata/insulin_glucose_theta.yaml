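# Population parameter values of the insulin-glucose panel example.
c_xx: 0.05
c_xy: 0.4
c_yx: -0.6
c_yy: 1.2
psi_x1x1: 131.76
psi_y1y1: 632.94
psi_x1y1: 254.12
psi_xx: 20
psi_yy: 40
psi_xy: 3
psi_x1x2: 15
psi_x2x3: 2
psi_y1y2: 35
psi_y2y3: 10
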