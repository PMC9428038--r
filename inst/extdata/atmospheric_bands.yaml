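# Synthetic atmospheric reference line lists (per species), used both to
# contaminate phantom spectra and as the reference set for least-squares
# suppression. Amplitudes are relative within a species; the phantom's
# atmospheric_level scales the whole set.
#
# CO2: asymmetric-stretch doublet near 2360/2340 cm^-1 plus the bending
# mode at 668 cm^-1 (the only CO2 feature inside the fingerprint window).
# H2O: a coarse comb of rotational-vibrational lines across the bending
# region 1900-1300 cm^-1.
co2:
  - {center_cm1: 2360, fwhm_cm1: 22, amplitude: 1.00, shape: lorentzian}
  - {center_cm1: 2340, fwhm_cm1: 20, amplitude: 0.80, shape: lorentzian}
  - {center_cm1: 668,  fwhm_cm1: 14, amplitude: 0.30, shape: lorentzian}
h2o:
  - {center_cm1: 1870, fwhm_cm1: 12, amplitude: 0.35, shape: lorentzian}
  - {center_cm1: 1844, fwhm_cm1: 12, amplitude: 0.45, shape: lorentzian}
  - {center_cm1: 1792, fwhm_cm1: 12, amplitude: 0.55, shape: lorentzian}
  - {center_cm1: 1734, fwhm_cm1: 12, amplitude: 0.60, shape: lorentzian}
  - {center_cm1: 1700, fwhm_cm1: 12, amplitude: 0.75, shape: lorentzian}
  - {center_cm1: 1670, fwhm_cm1: 10, amplitude: 0.85, shape: lorentzian}
  - {center_cm1: 1616, fwhm_cm1: 10, amplitude: 1.00, shape: lorentzian}
  - {center_cm1: 1576, fwhm_cm1: 10, amplitude: 0.85, shape: lorentzian}
  - {center_cm1: 1540, fwhm_cm1: 10, amplitude: 0.70, shape: lorentzian}
  - {center_cm1: 1508, fwhm_cm1: 10, amplitude: 0.65, shape: lorentzian}
  - {center_cm1: 1472, fwhm_cm1: 10, amplitude: 0.55, shape: lorentzian}
  - {center_cm1: 1436, fwhm_cm1: 10, amplitude: 0.45, shape: lorentzian}
  - {center_cm1: 1396, fwhm_cm1: 12, amplitude: 0.35, shape: lorentzian}
  - {center_cm1: 1340, fwhm_cm1: 12, amplitude: 0.25, shape: lorentzian}
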