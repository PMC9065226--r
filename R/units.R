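# Centralised unit conversions.
#
# Public interfaces speak clinical units: MBq, mL, mL/h, minutes, mm for
# radii, cm for axial distances, Pa.s, g/cm3, uSv/h (mSv/h for chart levels).
# All internal kinematics run in mm, minutes and MBq; every conversion goes
# through this table so there is exactly one place to get it wrong.
.units <- list(
  # flow: mL/h -> mm3/min
  mlh_to_mm3min = function(q) q * 1000 / 60,
  # flow: mL/h -> mm3/s
  mlh_to_mm3s = function(q) q * 1000 / 3600,
  cm_to_mm = function(x) x * 10,
  mm_to_cm = function(x) x / 10,
  mm_s_to_mm_min = function(v) v * 60,
  ml_to_mm3 = function(v) v * 1000,
  mm3_to_ml = function(v) v / 1000,
  msvh_to_usvh = function(x) x * 1000
)
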