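# Placeholder thermal-performance parameter sets for the three potato tuber
# moth species, producing biologically plausible curves (thermal optimum in
# the 15-20 deg C range, survival in [0,1], development in 1/day). These are
# synthetic stand-ins for tests and worked examples; users supply
# literature-fitted values (e.g. Crespo-Perez et al. 2011) for real analyses.
# Schoolfield parameters: d rate at 298.16 K; e,f,h energy-like (cal/mol,
# R = 1.987); g,i inactivation temperatures (Kelvin).
# Fecundity parameters: o baseline eggs, p peak increment, q peak temp (C),
# r width (C), s shape (>1).
phthorimaea_operculella:
  survival:    {d: 0.95, e: 8000,  f: -120000, g: 283.0, h: 140000, i: 293.0}
  development: {d: 0.10, e: 15000, f: -90000,  g: 281.5, h: 110000, i: 292.0}
  fecundity:   {o: 5, p: 120, q: 16, r: 4, s: 3}
tecia_solanivora:
  survival:    {d: 0.90, e: 9000,  f: -110000, g: 282.0, h: 130000, i: 291.5}
  development: {d: 0.09, e: 14000, f: -95000,  g: 281.0, h: 120000, i: 291.0}
  fecundity:   {o: 8, p: 150, q: 15, r: 3.5, s: 2.5}
symmetrischema_tangolias:
  survival:    {d: 0.92, e: 8500,  f: -115000, g: 282.5, h: 135000, i: 292.5}
  development: {d: 0.11, e: 16000, f: -85000,  g: 282.0, h: 115000, i: 293.0}
  fecundity:   {o: 6, p: 100, q: 17, r: 4.5, s: 3}
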