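## Internal unit system
##
## All public values are expressed in a single consistent unit system:
##   length       micrometre (um)
##   time         millisecond (ms)
##   potential    millivolt (mV)
##   current      nanoampere (nA)
##   resistance   megaohm (MOhm)        (1/MOhm = uS, so nA = uS * mV)
##   capacitance  nanofarad (nF)        (nF/ms = uS)
##   conductivity siemens per metre (S/m)
##   frequency    hertz (Hz)
## Specific membrane parameters keep their conventional units (Rm in Ohm*cm^2,
## Ra in Ohm*cm, Cm in uF/cm^2) and are converted on assembly.
##
## In this system the point-source kernel is exactly
##   Ve [mV] = I [nA] / (4 * pi * sigma [S/m] * r [um])
## with no extra numerical factor.

## total membrane conductance of a cylinder, uS
.membrane_conductance <- function(area_um2, rm_ohmcm2) {
  area_um2 / rm_ohmcm2 * 1e-2
}

## total membrane capacitance of a cylinder, nF
.membrane_capacitance <- function(area_um2, cm_uFcm2) {
  area_um2 * cm_uFcm2 * 1e-5
}

## axial resistance of a cylinder, MOhm
.axial_resistance <- function(length_um, diam_um, ra_ohmcm) {
  4 * ra_ohmcm * length_um * 1e-2 / (pi * diam_um^2)
}

## angular frequency in rad/ms for f in Hz
.omega_ms <- function(f_hz) 2 * pi * f_hz * 1e-3

## membrane time constant in ms
.tau_m_ms <- function(rm_ohmcm2, cm_uFcm2) rm_ohmcm2 * cm_uFcm2 * 1e-3

## DC length constant in um: lambda = sqrt(d * Rm / (4 * Ra))
.lambda_um <- function(diam_um, rm_ohmcm2, ra_ohmcm) {
  sqrt(diam_um * rm_ohmcm2 * 1e4 / (4 * ra_ohmcm))
}
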