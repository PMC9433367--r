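# Six-variable cross-lagged panel model of blood insulin (X, mcIU/ml)
# and blood glucose (Y, mg/dl) at three occasions.  Labels shared
# across edges impose time-constant coefficients; bidirected
# self-pairs declare error variances.
variables: [X1, Y1, X2, Y2, X3, Y3]
directed:
  - [X1, X2, c_xx]
  - [Y1, X2, c_xy]
  - [X1, Y2, c_yx]
  - [Y1, Y2, c_yy]
  - [X2, X3, c_xx]
  - [Y2, X3, c_xy]
  - [X2, Y3, c_yx]
  - [Y2, Y3, c_yy]
bidirected:
  - [X1, X1, psi_x1x1]
  - [Y1, Y1, psi_y1y1]
  - [X1, Y1, psi_x1y1]
  - [X2, X2, psi_xx]
  - [X3, X3, psi_xx]
  - [Y2, Y2, psi_yy]
  - [Y3, Y3, psi_yy]
  - [X2, Y2, psi_xy]
  - [X3, Y3, psi_xy]
  - [X1, X2, psi_x1x2]
  - [X2, X3, psi_x2x3]
  - [Y1, Y2, psi_y1y2]
  - [Y2, Y3, psi_y2y3]
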