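#' @import methods
#' @importFrom stats setNames
NULL

## Central S4 objects of the package. Validity methods encode the hard
## physical invariants; everything tabular (features, labels, ROI tables,
## cohort count tables) stays a plain data.frame.

#' Conductances and kinetics of the two-compartment neuron/glia model
#'
#' A `ModelParams` object holds every constant of the conductance-based
#' model: passive properties of the neuronal and glial compartments,
#' spiking (Na/K) conductances with adaptation, the T-type Ca2+ conductance
#' of each compartment, the Ca pool and SK conductance, the optional
#' H (sag) conductance, the CNG-like glial conductance with its slow gate,
#' the gap-junction conductance and the Ornstein-Uhlenbeck noise amplitude.
#' Values live in a single named numeric vector; use [modelParams()] to
#' construct one from a phenotype preset and [param()] to read a value.
#'
#' @slot values Named numeric vector of model constants (units documented
#'   in [modelParams()]).
#' @seealso [modelParams()], [applyDrug()], [simulateCell()]
#' @export
setClass("ModelParams", representation(values = "numeric"))

setValidity("ModelParams", function(object) {
  v <- object@values
  need <- .paramNames()
  miss <- setdiff(need, names(v))
  if (length(miss)) return(paste("missing parameters:", paste(miss, collapse = ", ")))
  if (anyNA(v) || any(!is.finite(v))) return("all parameters must be finite")
  gpos <- c("g_leak_n", "g_leak_g", "g_Na", "g_K", "g_T", "g_T_g", "g_SK",
            "g_H", "g_CNG", "g_gap", "g_adapt")
  if (any(v[gpos] < 0)) return("conductances must be >= 0")
  if (v["C_n"] <= 0 || v["C_g"] <= 0) return("capacitances must be > 0")
  if (v["tau_Ca"] <= 0) return("tau_Ca must be > 0")
  if (v["beta"] <= 0) return("CNG deactivation rate beta must be > 0")
  if (v["noise_sigma"] < 0) return("noise_sigma must be >= 0")
  TRUE
})

#' Current-step stimulation protocol
#'
#' Describes a single current-clamp step: holding level, step amplitude and
#' timing, total simulated/observed time and the integration step used by
#' the simulator.
#'
#' @slot hold_mV Holding potential (mV); `NA` means the cell rests freely
#'   (no bias current), as for spontaneous-activity recordings.
#' @slot amp_pA Step amplitude (pA, signed; negative = hyperpolarizing).
#' @slot t_on,t_off Step onset/offset (s) relative to trace start.
#' @slot t_total Total trace duration (s).
#' @slot dt Integration step (ms).
#' @seealso [stepProtocol()]
#' @export
setClass("StepProtocol",
         representation(hold_mV = "numeric", amp_pA = "numeric",
                        t_on = "numeric", t_off = "numeric",
                        t_total = "numeric", dt = "numeric"))

setValidity("StepProtocol", function(object) {
  if (length(object@amp_pA) != 1 || !is.finite(object@amp_pA))
    return("amp_pA must be a finite scalar")
  if (!(object@t_on < object@t_off)) return("need t_on < t_off")
  if (!(object@t_off < object@t_total)) return("need t_off < t_total")
  if (object@dt <= 0) return("integration step dt must be > 0")
  if (object@t_on < 0) return("t_on must be >= 0")
  TRUE
})

#' Uniformly sampled membrane-potential trace
#'
#' A voltage time series with its injected-current channel and metadata.
#' Samples run from t = 0 at `1/fs` spacing.
#'
#' @slot fs Sampling rate (Hz); default 20000.
#' @slot v_mV Voltage samples (mV).
#' @slot i_pA Injected-current samples (pA), same length as `v_mV`.
#' @slot meta List: cell id, compartment (`"neuron"` or `"non_neuron"`),
#'   drug, protocol fields, seed.
#' @seealso [voltageTrace()], [simulateCell()], [readTrace()]
#' @export
setClass("VoltageTrace",
         representation(fs = "numeric", v_mV = "numeric", i_pA = "numeric",
                        meta = "list"))

setValidity("VoltageTrace", function(object) {
  if (length(object@fs) != 1 || object@fs <= 0) return("fs must be a positive scalar")
  if (length(object@v_mV) != length(object@i_pA))
    return("v_mV and i_pA must have equal length")
  if (length(object@v_mV) < 2) return("trace must contain at least 2 samples")
  if (anyNA(object@v_mV) || any(!is.finite(object@v_mV)))
    return("voltage samples must be finite")
  if (anyNA(object@i_pA) || any(!is.finite(object@i_pA)))
    return("current samples must be finite")
  TRUE
})

#' Simultaneously recorded neuron / non-neuron trace pair
#'
#' Pre-junctional (neuron) and post-junctional (non-neuronal) voltage traces
#' on an identical time base, as produced by [simulatePair()] or assembled
#' from sweep-averaged double recordings.
#'
#' @slot pre,post [VoltageTrace-class] objects with identical `fs` and length.
#' @slot n_sweeps Number of sweeps averaged into each trace (1-50).
#' @seealso [simulatePair()], [synchrony()]
#' @export
setClass("PairedTraces",
         representation(pre = "VoltageTrace", post = "VoltageTrace",
                        n_sweeps = "numeric"))

setValidity("PairedTraces", function(object) {
  if (object@pre@fs != object@post@fs) return("pre/post sampling rates differ")
  if (length(object@pre@v_mV) != length(object@post@v_mV))
    return("pre/post traces differ in length")
  if (object@n_sweeps < 1 || object@n_sweeps > 50)
    return("n_sweeps must lie in [1, 50]")
  TRUE
})

#' Configuration of a synthetic recording cohort
#'
#' Describes one simulated group of cells: its size, the probability that a
#' cell carries the long-RDP phenotype or the HF-firing phenotype, the
#' relative parameter jitter applied around the phenotype presets, and the
#' seed making the cohort reproducible.
#'
#' @slot group Group label (e.g. `"naive"`, `"susceptible"`, `"resilient"`).
#' @slot n_cells Number of cells (>= 1).
#' @slot p_long Probability that a cell is a long-RDP phenotype.
#' @slot p_hf Probability that a cell is an HF-firing phenotype.
#' @slot jitter_sd Relative SD of lognormal jitter on key conductances.
#' @slot seed Integer seed.
#' @seealso [cohortConfig()], [makeCohort()]
#' @export
setClass("CohortConfig",
         representation(group = "character", n_cells = "numeric",
                        p_long = "numeric", p_hf = "numeric",
                        jitter_sd = "numeric", seed = "numeric"))

setValidity("CohortConfig", function(object) {
  if (object@n_cells < 1 || object@n_cells != round(object@n_cells))
    return("n_cells must be a positive integer")
  if (object@p_long < 0 || object@p_long > 1) return("p_long must lie in [0, 1]")
  if (object@p_hf < 0 || object@p_hf > 1) return("p_hf must lie in [0, 1]")
  if (object@jitter_sd < 0) return("jitter_sd must be >= 0")
  TRUE
})
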