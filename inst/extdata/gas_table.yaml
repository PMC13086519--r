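# Dimensionless Henry solubility constants (C_liquid / C_gas at equilibrium)
# for water at 20 C, and the gas-liquid transfer mode. "equilibrium" means the
# vial is stirred vigorously enough that the two phases are always at
# equilibrium; a numeric kla (h^-1) opts into transfer-limited estimates.
# Sources: Ostwald solubility coefficients tabulated in Sander (2015),
# Atmos. Chem. Phys. 15:4399 (compilation of Henry's law constants),
# converted to the dimensionless ratio at 293 K.
# (species keys are quoted: bare NO is a YAML 1.1 boolean)
"O2":
  henry_cc: 0.033
  kla: equilibrium
"NO":
  henry_cc: 0.047
  kla: equilibrium
"N2O":
  henry_cc: 0.632
  kla: equilibrium
"N2":
  henry_cc: 0.016
  kla: equilibrium
"He":
  henry_cc: 0.0086
  kla: equilibrium
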