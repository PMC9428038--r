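# Default phantom band sets for the three lung tumour subtypes.
# All classes share the same five biological band positions (lipid ester
# C=O ~1740, amide I ~1655, amide II ~1545, asymmetric phosphate ~1240,
# symmetric phosphate / C-O ~1080 cm^-1); classes differ only in relative
# amplitudes (arbitrary absorbance units). Minimum between-class amplitude
# difference on any single band is 0.15 absorbance units.
SQ:
  - {center_cm1: 1740, fwhm_cm1: 26, amplitude: 0.30, shape: gaussian}
  - {center_cm1: 1655, fwhm_cm1: 42, amplitude: 1.00, shape: gaussian}
  - {center_cm1: 1545, fwhm_cm1: 36, amplitude: 0.55, shape: gaussian}
  - {center_cm1: 1240, fwhm_cm1: 34, amplitude: 0.25, shape: gaussian}
  - {center_cm1: 1080, fwhm_cm1: 46, amplitude: 0.30, shape: lorentzian}
LUAD:
  - {center_cm1: 1740, fwhm_cm1: 26, amplitude: 0.45, shape: gaussian}
  - {center_cm1: 1655, fwhm_cm1: 42, amplitude: 0.85, shape: gaussian}
  - {center_cm1: 1545, fwhm_cm1: 36, amplitude: 0.40, shape: gaussian}
  - {center_cm1: 1240, fwhm_cm1: 34, amplitude: 0.40, shape: gaussian}
  - {center_cm1: 1080, fwhm_cm1: 46, amplitude: 0.45, shape: lorentzian}
SCLC:
  - {center_cm1: 1740, fwhm_cm1: 26, amplitude: 0.15, shape: gaussian}
  - {center_cm1: 1655, fwhm_cm1: 42, amplitude: 0.90, shape: gaussian}
  - {center_cm1: 1545, fwhm_cm1: 36, amplitude: 0.55, shape: gaussian}
  - {center_cm1: 1240, fwhm_cm1: 34, amplitude: 0.55, shape: gaussian}
  - {center_cm1: 1080, fwhm_cm1: 46, amplitude: 0.65, shape: lorentzian}
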