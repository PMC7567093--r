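{
 "adipose": {
  "density_g_cm3": 0.93,
  "provenance": "Hammerstein adipose composition; NIST elemental tables"
 },
 "glandular": {
  "density_g_cm3": 1.04,
  "provenance": "Hammerstein glandular composition; NIST elemental tables"
 },
 "polyethylene": {
  "density_g_cm3": 0.93,
  "provenance": "(C2H4)n at rho = 0.93 g/cm^3; NIST elemental tables"
 },
 "breast_icru44": {
  "density_g_cm3": 1.02,
  "provenance": "ICRU Report 44 breast tissue; NIST elemental tables"
 },
 "air": {
  "density_g_cm3": 0.00120479,
  "provenance": "NIST dry air (near sea level) material table"
 }
}
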