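# Group-level prior specification for the hierarchical ex-Gaussian race
# model. Positive parameters (all mu/sigma/tau, in seconds) get truncated
# normal priors on the group mean and half-normal-style priors on the group
# SD; the failure probabilities are modelled on the probit scale.
#
# The three location means (mu_go_match 1.5 s, mu_go_mismatch 1.5 s,
# mu_stop 1 s) reflect slowed reaction times in older adults. All other
# locations and every scale are implementation defaults chosen to be weakly
# informative on the seconds scale.
mean:
  mu_stop:            {loc: 1.0,  scale: 1.0}
  sigma_stop:         {loc: 0.2,  scale: 1.0}
  tau_stop:           {loc: 0.2,  scale: 1.0}
  mu_go_match:        {loc: 1.5,  scale: 1.0}
  sigma_go_match:     {loc: 0.2,  scale: 1.0}
  tau_go_match:       {loc: 0.2,  scale: 1.0}
  mu_go_mismatch:     {loc: 1.5,  scale: 1.0}
  sigma_go_mismatch:  {loc: 0.2,  scale: 1.0}
  tau_go_mismatch:    {loc: 0.2,  scale: 1.0}
  p_tf:               {loc: -1.5, scale: 1.0}   # probit scale
  p_gf:               {loc: -1.5, scale: 1.0}   # probit scale
sd:
  mu_stop:            {loc: 0.0,  scale: 0.5}
  sigma_stop:         {loc: 0.0,  scale: 0.5}
  tau_stop:           {loc: 0.0,  scale: 0.5}
  mu_go_match:        {loc: 0.0,  scale: 0.5}
  sigma_go_match:     {loc: 0.0,  scale: 0.5}
  tau_go_match:       {loc: 0.0,  scale: 0.5}
  mu_go_mismatch:     {loc: 0.0,  scale: 0.5}
  sigma_go_mismatch:  {loc: 0.0,  scale: 0.5}
  tau_go_mismatch:    {loc: 0.0,  scale: 0.5}
  p_tf:               {loc: 0.0,  scale: 1.0}
  p_gf:               {loc: 0.0,  scale: 1.0}
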