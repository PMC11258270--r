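# Default parameters for the glucotwin pancreas-liver MPS model.
#
# Units: time h, volumes L, glucose mmol (mmol/L), insulin mIU (mIU/L).
#
# Geometry reflects the chip platform (300 ul medium per compartment,
# 15 ul GTT samples, 4.94 ul/min mean inter-compartment flow). The kinetic
# constants below are package ASSUMPTIONS: they are not printed in the
# source study and were chosen once, at design time, so that the default
# model reproduces the qualitative on-chip GTT behaviour (an 11 mM load
# cleared to ~2-3 mM within 48 h early in co-culture with an insulin
# response of tens of mIU/L, and a blunted response late in co-culture
# under the diseased condition). Every value is overridable via
# default_parameters(...) / update_parameters().
hypothesis: H2
geometry:
  V_m_liver: 3.0e-4            # L, medium in liver compartment
  V_m_pancreas: 3.0e-4         # L, medium in pancreas compartment
  V_HepaRG_spheroids: 2.4e-6   # L, 40 spheroids x 24,000 cells x ~2.5 pL
  Q: 2.964e-4                  # L/h  (= 4.94 ul/min)
  V_sample_liver: 1.5e-5       # L, 15 ul GTT draw
  V_sample_pancreas: 1.5e-5    # L
fast:
  E_G0: 0.3            # 1/h, insulin-independent glucose disposal
  S_I0: 0.1            # L/mIU/h, initial insulin sensitivity
  I_max_Si: 0.9        # -, max fractional S_I reduction by hyperglycemia
  EC50_Si: 600.0       # mmol h/L, half-max excess-glucose integral
  EGP: 0.0             # mmol/L/h, endogenous glucose production (fixed 0)
  sigma_max: 4.0e+5    # mIU/L/h per unit beta-cell volume
  alpha: 28224.0       # h^2, secretion capacity halves at sqrt(alpha)=168 h
  EC50_I: 10.0         # mmol/L, glucose at half-max insulin secretion
  k_elimination_I_spheroids: 5.0  # 1/h, hepatic insulin elimination
  G_normo: 5.5         # mmol/L, normoglycemic reference
slow:
  k_v: 1.0             # -, scaling of beta-cell volume dynamics
  d_0: 2.5e-3          # 1/h, death rate at zero glucose
  r1: 6.3e-4           # L/mmol/h, linear replication/apoptosis composite
  r2: 3.24e-5          # L^2/mmol^2/h, quadratic composite
  tau_slow: 24.0       # h, averaging time scale of G_slow
  V_beta_0: 8.8e-9     # L, initial beta-cell volume
h2:
  I_max_additional: 0.995  # -, max fractional S_I reduction, extra factor
  EC50_additional: 30.0    # h, time at half-max additional reduction
offsets:
  dG_d1: 0.0           # mmol/L, day-1 exchange glucose offset
  dG_d13: 0.0          # mmol/L, day-13 exchange glucose offset
  dI_d1: 0.0           # mIU/L, day-1 exchange insulin offset
  dI_d13: 0.0          # mIU/L, day-13 exchange insulin offset
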