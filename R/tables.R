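#' Fixed model constants
#'
#' Constants of the leaky integrate-and-fire basal ganglia model that are not
#' subject to per-model variation: neuron counts per channel, input-pool
#' sizes, afferent baseline rates, alpha-PSP amplitudes and half-times,
#' passive-cable properties, dendritic geometry, projection fractions,
#' membrane time constants and the refractory period.
#'
#' Counts per channel follow the 1/5000 channel-fraction convention of the
#' model (each channel is 1/5000 of the corresponding primate population).
#'
#' @return A named list of constants; see Details in the package vignette.
#' @export
bg_fixed_params <- function() {
  list(
    nuclei = c("MSN", "FSI", "STN", "GPe", "GPi"),
    inputs = c("CSN", "PTN", "CMPf"),
    # neurons per channel
    n = c(MSN = 10576, FSI = 212, STN = 32, GPe = 100, GPi = 56),
    # afferent pool size per input population (per channel for CSN/PTN,
    # one shared pool for CMPf)
    n_input = 12000,
    # afferent baseline rates (Hz)
    phi = c(CSN = 2, PTN = 15, CMPf = 4),
    # alpha-PSP amplitudes (mV) and half-times (ms)
    A = c(AMPA = 1, NMDA = 0.025, GABAA = 0.25),
    D = c(AMPA = 5, NMDA = 100, GABAA = 5),
    # passive cable: membrane resistance (Ohm cm^2), intracellular
    # resistivity (Ohm cm)
    R_m = 20000,
    R_i = 200,
    # mean dendritic extent (um) and diameter (um)
    l = c(MSN = 619, FSI = 961, STN = 750, GPe = 865, GPi = 1132),
    d = c(MSN = 1, FSI = 1.5, STN = 1.5, GPe = 1.7, GPi = 1.2),
    # membrane time constants (ms), refractory period (ms)
    tau_m = c(MSN = 13, FSI = 16, STN = 26, GPe = 14, GPi = 14),
    t_ref = 2,
    # redundancy: synaptic contacts per axon per dendritic field
    rho = 3,
    channel_fraction = 1 / 5000
  )
}

#' Optimized anatomical parameter ranges
#'
#' Per-projection bouton-count (`alpha`) and receptor-location (`p`,
#' fraction of dendritic length) ranges, per-nucleus firing-threshold
#' (`theta`) ranges, and projection fractions (`P`), defining the anatomical
#' plausibility envelope of the model.  Bouton numbers for the afferent
#' populations (CSN, PTN, CM/Pf) assume a 12,000-neuron input pool.
#'
#' The internal wiring comprises exactly 12 projections (MSN to MSN/GPe/GPi,
#' FSI to MSN/FSI, STN to MSN/FSI/GPe/GPi, GPe to STN/GPe/GPi) plus 10
#' afferent projections (CSN to MSN/FSI, PTN to MSN/FSI/STN, CM/Pf to all
#' five nuclei).  Projections with no documented receptor-location interval
#' default to the whole dendrite (0-1); the PTN-to-STN bouton count, for
#' which no range is documented, defaults to 0-1 as for the other sparse
#' afferents onto the STN.
#'
#' @return A list with elements `projections` (data.frame: src, tgt,
#'   alpha_lo, alpha_hi, p_lo, p_hi, P, pattern, transmitter) and `theta`
#'   (data.frame: nucleus, lo, hi).
#' @export
bg_param_ranges <- function() {
  pr <- read.csv(text = "
src,tgt,alpha_lo,alpha_hi,p_lo,p_hi,P,pattern,transmitter
MSN,MSN,209,627,0.64,0.88,1,focused,GABA
MSN,GPe,171,203,0.48,0.60,1,focused,GABA
MSN,GPi,166,288,0.30,0.59,0.82,focused,GABA
FSI,MSN,2172,4928,0.00,0.19,1,focused,GABA
FSI,FSI,26,140,0.00,1.00,1,focused,GABA
STN,MSN,0,109,0.00,1.00,0.17,diffuse,glutamate
STN,FSI,0,92,0.00,1.00,0.17,diffuse,glutamate
STN,GPe,291,454,0.23,0.53,0.83,diffuse,glutamate
STN,GPi,159,239,0.45,0.59,0.72,diffuse,glutamate
GPe,STN,19,20,0.28,0.60,1,focused,GABA
GPe,GPe,37,38,0.00,0.01,0.84,focused,GABA
GPe,GPi,16,17,0.00,0.15,0.84,focused,GABA
CSN,MSN,248,313,0.80,1.00,1,focused,glutamate
CSN,FSI,4,9,0.80,0.96,1,focused,glutamate
PTN,MSN,4,9,0.76,1.00,1,focused,glutamate
PTN,FSI,0,1,0.00,1.00,1,focused,glutamate
PTN,STN,0,1,0.63,1.00,1,focused,glutamate
CMPf,MSN,5,15,0.26,0.59,1,diffuse,glutamate
CMPf,FSI,2,4,0.00,0.17,1,diffuse,glutamate
CMPf,STN,0,1,0.00,1.00,1,diffuse,glutamate
CMPf,GPe,0,1,0.00,1.00,1,diffuse,glutamate
CMPf,GPi,0,1,0.00,1.00,1,diffuse,glutamate
", stringsAsFactors = FALSE, strip.white = TRUE)
  th <- data.frame(
    nucleus = c("MSN", "FSI", "STN", "GPe", "GPi"),
    lo = c(28, 11, 24, 6, 5),
    hi = c(30, 21, 27, 12, 7),
    stringsAsFactors = FALSE
  )
  list(projections = pr, theta = th)
}

#' Default tonic inputs
#'
#' Default tonic input potentials V_C (mV) per nucleus.  Tonic inputs are
#' the calibration degrees of freedom of the spiking model (they are found
#' per parameterization by the hypersphere grid search of
#' [hypersphere_calibrate()]); these defaults were obtained by one coarse
#' calibration pass of the package against physiological rest-rate
#' ballparks and give tonically active pallidal/subthalamic populations and
#' near-silent striatal projection neurons.
#'
#' @return Named numeric vector of tonic inputs (mV).
#' @export
bg_default_vc <- function() {
  c(MSN = 21, FSI = 2.5, STN = 11, GPe = 0, GPi = 7)
}

# internal: projection id "SRC.TGT"
proj_id <- function(src, tgt) paste(src, tgt, sep = "->")
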