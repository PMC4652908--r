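# Alternate attractor parameterization (figure-caption variant of the
# attractor replication): stronger synaptic peak and a smaller ventral
# input gain than the default parameter table. Load with read_config();
# every block not listed here inherits the defaults.
attractor:
  n_x: 9
  n_y: 10
  I: 0.8
  T_inhib: 0.05
  alpha_moving: 1.4e-3
  alpha_static: 0.9e-4
  sigma: 0.24
  gamma: 0
  tau: 0.8
  eta: 0.1
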