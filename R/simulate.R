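#' @include AllGenerics.R
#' @importFrom stats uniroot rbinom rnorm runif
#' @useDynLib lhbRDP, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

## ---------------------------------------------------------------------------
## parameter dictionary and phenotype presets
## ---------------------------------------------------------------------------

.paramNames <- function() names(.baseParams())

# Model constants. Units: capacitance pF, conductance nS, voltage mV, time
# constants ms, Ca arbitrary concentration units (uM-like), rates alpha/beta
# in 1/s, noise amplitude pA.
.baseParams <- function() c(
  C_n = 40, C_g = 25,
  g_leak_n = 2, E_leak_n = -60, g_leak_g = 18, E_leak_g = -85,
  g_Na = 1200, E_Na = 55, g_K = 200, E_K = -90,
  g_T = 60, g_T_g = 0, E_Ca = 120,
  vm_T = -50, km_T = 6, vh_T = -75, kh_T = 7,
  tauh_min = 65, tauh_amp = 400, tauh_vmid = -65, tauh_k = 6,
  g_SK = 5, K_Ca = 1.0, n_Hill = 4, k_Ca = 3e-5, tau_Ca = 40,
  sk_ca_coupling = 1,
  g_adapt = 3, va_adapt = -45, ka_adapt = 5, tau_adapt = 150,
  tau_nap = 800, v_nap = -40, k_nap = 4,
  g_H = 1.5, E_H = -43, v_r = -75, k_r = 5.5, tau_r = 150,
  vm_Tg = -67, vh_Tg = -82,
  g_CNG = 0, E_CNG = 0, alpha = 25, beta = 0.55, theta_CNG = -24,
  tau_gate = 10,
  g_gap = 2.5, noise_sigma = 0, tau_ou = 5, phi = 5, na_shift = 0,
  seed = 0
)

# Named phenotype presets, applied on top of the base set (which is itself
# the short-RDP / HF-firing phenotype). Combined phenotypes stack presets,
# e.g. modelParams(c("long_rdp", "lf")).
.presets <- function() list(
  short_rdp = c(),
  long_rdp  = c(g_CNG = 40, g_T_g = 25),
  hf        = c(),
  lf        = c(v_nap = -48, tau_nap = 300),
  sag       = c(g_H = 6),
  silent    = c(E_leak_n = -65, noise_sigma = 5),
  tonic     = c(E_leak_n = -52, noise_sigma = 5),
  burst     = c(E_leak_n = -63, noise_sigma = 8)
)

#' Construct model parameters from phenotype presets
#'
#' Builds a [ModelParams-class] object from one or more named presets, then
#' applies any explicit overrides. Available presets: `"short_rdp"` (the
#' base set: T-type trigger + SK shortening, no CNG), `"long_rdp"` (adds
#' the glial T-type and CNG conductances that generate the seconds-long
#' plateau), `"hf"` / `"lf"` (weak / strong spike-frequency adaptation),
#' `"sag"` (adds the H conductance), `"silent"` / `"tonic"` / `"burst"`
#' (spontaneous-activity modes used at rest). Presets stack left to right.
#'
#' Key fields (units): `C_n`, `C_g` capacitance (pF); `g_leak_n`,
#' `g_leak_g` leak conductance (nS) with reversals `E_leak_n`, `E_leak_g`
#' (mV); `g_Na`, `g_K` spike conductances (nS); `g_T`, `g_T_g` T-type
#' Ca2+ conductance of neuron and glial compartment (nS); `g_SK` SK
#' conductance (nS) gated by the Ca pool (half-activation `K_Ca`, Hill
#' coefficient `n_Hill`; influx scaling `k_Ca` per pA of T current, decay
#' `tau_Ca` ms); `g_H` sag conductance (nS); `g_CNG` CNG-like glial
#' conductance (nS, reversal `E_CNG` = 0 mV) with slow gate charged at
#' rate `alpha` (1/s) while the glial voltage exceeds `theta_CNG` and
#' deactivating at rate `beta` (1/s); `g_gap` gap-junction conductance
#' (nS); `noise_sigma` OU current-noise amplitude (pA, time constant
#' `tau_ou` ms); `seed` integer noise seed.
#'
#' @param phenotype Character vector of preset names, applied in order.
#' @param ... Named numeric overrides of individual parameters.
#' @return A validated [ModelParams-class] object.
#' @examples
#' modelParams("long_rdp")
#' modelParams(c("long_rdp", "lf"), g_gap = 3)
#' @export
modelParams <- function(phenotype = "short_rdp", ...) {
  v <- .baseParams()
  pres <- .presets()
  for (ph in phenotype) {
    if (!ph %in% names(pres))
      stop("unknown phenotype preset: ", ph,
           " (available: ", paste(names(pres), collapse = ", "), ")")
    upd <- pres[[ph]]
    if (length(upd)) v[names(upd)] <- upd
  }
  dots <- c(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(v))
    if (length(bad)) stop("unknown model parameter(s): ", paste(bad, collapse = ", "))
    v[names(dots)] <- dots
  }
  new("ModelParams", values = v)
}

#' Construct a current-step protocol
#'
#' Defaults describe the study protocol: cells held at -60 mV, 1 s steps,
#' and for hyperpolarizing steps an observation window long enough to
#' capture plateaus lasting several seconds.
#'
#' @param hold_mV Holding potential (mV), or `NA` to leave the cell at rest.
#' @param amp_pA Step amplitude (pA; negative = hyperpolarizing).
#' @param t_on,t_off Step onset/offset (s).
#' @param t_total Total trace length (s). For RDP measurement keep at
#'   least 5 s after `t_off`.
#' @param dt Integration step (ms); the default 0.025 ms resolves Na spikes.
#' @return A validated [StepProtocol-class].
#' @examples
#' stepProtocol(amp_pA = -100)
#' @export
stepProtocol <- function(hold_mV = -60, amp_pA = -100, t_on = 1, t_off = 2,
                         t_total = 12, dt = 0.025) {
  new("StepProtocol", hold_mV = as.numeric(hold_mV), amp_pA = amp_pA, t_on = t_on,
      t_off = t_off, t_total = t_total, dt = dt)
}

#' Construct a voltage trace
#'
#' @param v_mV Voltage samples (mV).
#' @param fs Sampling rate (Hz).
#' @param i_pA Injected current samples (pA); recycled scalar allowed.
#' @param meta Metadata list.
#' @return A validated [VoltageTrace-class].
#' @examples
#' voltageTrace(rep(-60, 1000), fs = 20000)
#' @export
voltageTrace <- function(v_mV, fs = 20000, i_pA = 0, meta = list()) {
  if (length(i_pA) == 1) i_pA <- rep(i_pA, length(v_mV))
  new("VoltageTrace", fs = fs, v_mV = as.numeric(v_mV),
      i_pA = as.numeric(i_pA), meta = meta)
}

#' Construct a cohort configuration
#'
#' @param group Group label.
#' @param n_cells Number of cells.
#' @param p_long Probability of the long-RDP phenotype.
#' @param p_hf Probability of the HF-firing phenotype.
#' @param jitter_sd Relative (lognormal) SD of per-cell conductance jitter.
#' @param seed Integer seed; identical seeds give identical cohorts.
#' @return A validated [CohortConfig-class].
#' @export
cohortConfig <- function(group = "custom", n_cells, p_long, p_hf = 0.6,
                         jitter_sd = 0.1, seed = 1) {
  new("CohortConfig", group = group, n_cells = n_cells, p_long = p_long,
      p_hf = p_hf, jitter_sd = jitter_sd, seed = seed)
}

## ---------------------------------------------------------------------------
## drugs
## ---------------------------------------------------------------------------

# Each named drug maps to a fixed, documented parameter transformation.
.drugTable <- function() list(
  control       = function(v) v,
  ttx           = function(v) { v["g_Na"] <- 0; v },
  apamin        = function(v) { v["g_SK"] <- 0; v },
  z944          = function(v) { v["g_T"] <- 0; v["g_T_g"] <- 0; v },
  ni_high       = function(v) { v["g_T"] <- 0; v["g_T_g"] <- 0; v },
  ni_low        = function(v) { v["g_CNG"] <- 0.2 * v["g_CNG"]
                                v["g_T"] <- 0.8 * v["g_T"]
                                v["g_T_g"] <- 0.8 * v["g_T_g"]; v },
  lcd           = function(v) { v["g_CNG"] <- 0; v },
  carbenoxolone = function(v) { v["g_gap"] <- 0; v },
  mfa           = function(v) { v["g_gap"] <- 0; v },
  bapta         = function(v) { v["sk_ca_coupling"] <- 0; v },
  br_cgmp       = function(v) { v["beta"] <- 0.5 * v["beta"]; v }
)

#' Known drug conditions
#'
#' @return Character vector of recognised drug names: bath TTX (Na block),
#'   apamin (SK block), Z944 and high Ni2+ (T-type block), low Ni2+
#'   (partial CNG + mild T-type reduction), L-cis-diltiazem `"lcd"`
#'   (CNG block), carbenoxolone / meclofenamic acid `"mfa"` (gap-junction
#'   block), intracellular BAPTA (SK decoupled from Ca) and 8-bromo-cGMP
#'   `"br_cgmp"` (halved CNG deactivation rate, prolonging the plateau).
#' @examples
#' drugNames()
#' @export
drugNames <- function() names(.drugTable())

#' Apply a pharmacological condition to model parameters
#'
#' Pure function: returns a transformed copy, the input is untouched.
#'
#' @param params A [ModelParams-class] object.
#' @param drug One of [drugNames()].
#' @return A new [ModelParams-class].
#' @examples
#' param(applyDrug(modelParams("long_rdp"), "ttx"), "g_Na")
#' @export
applyDrug <- function(params, drug) {
  stopifnot(is(params, "ModelParams"))
  tab <- .drugTable()
  if (!is.character(drug) || length(drug) != 1 || !drug %in% names(tab))
    stop("unknown drug name: ", paste(drug, collapse = ", "),
         " (known: ", paste(names(tab), collapse = ", "), ")")
  new("ModelParams", values = tab[[drug]](params@values))
}

## ---------------------------------------------------------------------------
## steady state and integration
## ---------------------------------------------------------------------------

# order must match enum Par in src/rdp_model.cpp; alpha/beta converted 1/s -> 1/ms
.paramVector <- function(params) {
  v <- params@values
  c(v["C_n"], v["C_g"], v["g_leak_n"], v["E_leak_n"], v["g_leak_g"], v["E_leak_g"],
    v["g_Na"], v["E_Na"], v["g_K"], v["E_K"],
    v["g_T"], v["g_T_g"], v["E_Ca"], v["vm_T"], v["km_T"], v["vh_T"], v["kh_T"],
    v["tauh_min"], v["tauh_amp"], v["tauh_vmid"], v["tauh_k"],
    v["g_SK"], v["K_Ca"], v["n_Hill"], v["k_Ca"], v["tau_Ca"], v["sk_ca_coupling"],
    v["g_adapt"], v["va_adapt"], v["ka_adapt"], v["tau_adapt"],
    v["tau_nap"], v["v_nap"], v["k_nap"],
    v["g_H"], v["E_H"], v["v_r"], v["k_r"], v["tau_r"],
    v["vm_Tg"], v["vh_Tg"],
    v["g_CNG"], v["E_CNG"], v["alpha"] / 1000, v["beta"] / 1000, v["theta_CNG"],
    v["tau_gate"], v["g_gap"],
    v["noise_sigma"], v["tau_ou"], v["phi"], v["na_shift"])
}

.sigm <- function(v, vhalf, k) 1 / (1 + exp(-(v - vhalf) / k))

.gateSS <- function(v, p) {
  vs <- v + p["na_shift"]
  am_h <- 0.07 * exp(-(vs + 58) / 20)
  bm_h <- 1 / (1 + exp(-(vs + 28) / 10))
  x <- vs + 34
  am_n <- if (abs(x) < 1e-6) 0.1 else 0.01 * x / (1 - exp(-x / 10))
  bm_n <- 0.125 * exp(-(vs + 44) / 80)
  list(h = am_h / (am_h + bm_h), n = am_n / (am_n + bm_n),
       hT = 1 / (1 + exp((v - p["vh_T"]) / p["kh_T"])),
       a = .sigm(v, p["va_adapt"], p["ka_adapt"]),
       p = 1 / (1 + exp((v - p["v_nap"]) / p["k_nap"])),
       r = 1 / (1 + exp((v - p["v_r"]) / p["k_r"])))
}

.minfNa <- function(v, shift = 0) {
  v <- v + shift
  x <- v + 35
  am <- ifelse(abs(x) < 1e-6, 1, 0.1 * x / (1 - exp(-x / 10)))
  bm <- 4 * exp(-(v + 60) / 18)
  am / (am + bm)
}

# resting potential of the glial compartment given a fixed neuron voltage
# (CNG gate assumed closed: the rest must sit below theta_CNG)
.glialRest <- function(p, vn) {
  f <- function(vg) {
    mt <- .sigm(vg, p["vm_Tg"], p["km_T"])
    ht <- 1 / (1 + exp((vg - p["vh_Tg"]) / p["kh_T"]))
    -p["g_leak_g"] * (vg - p["E_leak_g"]) -
      p["g_T_g"] * mt^2 * ht * (vg - p["E_Ca"]) +
      p["g_gap"] * (vn - vg)
  }
  uniroot(f, c(-150, -30), tol = 1e-10)$root
}

# full initial state + holding bias current for a given holding potential
.steadyState <- function(params, hold_mV) {
  p <- params@values
  if (is.na(hold_mV)) {
    vn <- p["E_leak_n"]
    vg <- .glialRest(p, vn)
    g <- .gateSS(vn, p)
    st <- c(vn, g$h, g$n, g$hT, 0, g$a, g$p, g$r, vg,
            1 / (1 + exp((vg - p["vh_Tg"]) / p["kh_T"])), 0, vg)
    return(list(state = unname(st), i_hold = 0))
  }
  vn <- hold_mV
  vg <- .glialRest(p, vn)
  g <- .gateSS(vn, p)
  mt <- .sigm(vn, p["vm_T"], p["km_T"])
  i_t <- p["g_T"] * mt^2 * g$hT * (vn - p["E_Ca"])
  ca <- max(0, -p["k_Ca"] * i_t * p["tau_Ca"])
  ca_eff <- p["sk_ca_coupling"] * ca
  sk_open <- ca_eff^p["n_Hill"] / (ca_eff^p["n_Hill"] + p["K_Ca"]^p["n_Hill"])
  i_na <- p["g_Na"] * g$p * .minfNa(vn, p["na_shift"])^3 * g$h * (vn - p["E_Na"])
  i_k <- p["g_K"] * g$n^4 * (vn - p["E_K"])
  i_sk <- p["g_SK"] * sk_open * (vn - p["E_K"])
  i_ad <- p["g_adapt"] * g$a * (vn - p["E_K"])
  i_h <- p["g_H"] * g$r * (vn - p["E_H"])
  i_hold <- p["g_leak_n"] * (vn - p["E_leak_n"]) + i_na + i_k + i_t + i_sk +
    i_ad + i_h + p["g_gap"] * (vn - vg)
  st <- c(vn, g$h, g$n, g$hT, ca, g$a, g$p, g$r, vg,
          1 / (1 + exp((vg - p["vh_Tg"]) / p["kh_T"])), 0, vg)
  list(state = unname(st), i_hold = unname(i_hold))
}

.runModel <- function(params, protocol, fs, settle_ms) {
  stride <- 1000 / (fs * protocol@dt)
  if (abs(stride - round(stride)) > 1e-6)
    stop("sampling rate ", fs, " Hz is not an integer multiple of the ",
         "integration grid (dt = ", protocol@dt, " ms)")
  ss <- .steadyState(params, protocol@hold_mV)
  res <- .rdp_simulate_cpp(unname(.paramVector(params)), ss$state,
                           protocol@dt, settle_ms,
                           protocol@t_total * 1000, protocol@t_on * 1000,
                           protocol@t_off * 1000, protocol@amp_pA,
                           ss$i_hold, as.integer(round(stride)),
                           param(params, "seed"))
  if (isTRUE(res$diverged))
    stop(sprintf("numerical divergence (|V| > 200 mV) at t = %.1f ms; %s",
                 res$t_diverged_ms,
                 "check conductances or reduce dt"))
  res
}

#' Simulate a current-clamp recording from one model cell
#'
#' Integrates the two-compartment model under a step protocol and returns
#' the neuronal voltage trace. Holding at `hold_mV` is implemented as a
#' pre-computed constant bias current (as in manual current-clamp holding),
#' after which the model is settled briefly on the holding equilibrium;
#' with `hold_mV = NA` the cell is settled at its free resting state for
#' 3 s before recording starts. When the gap junction is open
#' (`g_gap > 0`) the simultaneously recorded glial trace is attached as
#' attribute `"non_neuron"`.
#'
#' Deterministic for a fixed `(params, protocol, drug)` triple: noise is
#' generated from `param(params, "seed")` by an internal generator, and
#' noise-free runs do not consume randomness at all.
#'
#' @param params A [ModelParams-class] object.
#' @param protocol A [StepProtocol-class] object.
#' @param drug A drug name from [drugNames()]; applied with [applyDrug()].
#' @param fs Output sampling rate (Hz; default 20000).
#' @param cell_id Identifier stored in the trace metadata.
#' @return A [VoltageTrace-class] (neuron compartment); glial companion
#'   trace in `attr(, "non_neuron")` when `g_gap > 0`.
#' @examples
#' tr <- simulateCell(modelParams("short_rdp"),
#'                    stepProtocol(amp_pA = -100, t_total = 8))
#' @export
simulateCell <- function(params, protocol, drug = "control", fs = 20000,
                         cell_id = "cell") {
  stopifnot(is(params, "ModelParams"), is(protocol, "StepProtocol"))
  params <- applyDrug(params, drug)
  settle <- if (is.na(protocol@hold_mV)) 3000 else 500
  res <- .runModel(params, protocol, fs, settle)
  meta <- list(cell_id = cell_id, compartment = "neuron", drug = drug,
               seed = param(params, "seed"),
               protocol = list(hold_mV = protocol@hold_mV,
                               amp_pA = protocol@amp_pA,
                               t_on = protocol@t_on, t_off = protocol@t_off,
                               t_total = protocol@t_total, dt = protocol@dt))
  tr <- new("VoltageTrace", fs = fs, v_mV = res$vn, i_pA = res$i, meta = meta)
  if (param(params, "g_gap") > 0) {
    gm <- meta; gm$compartment <- "non_neuron"
    attr(tr, "non_neuron") <- new("VoltageTrace", fs = fs, v_mV = res$vg,
                                  i_pA = rep(0, length(res$vg)), meta = gm)
  }
  tr
}

#' Simulate a paired neuron / non-neuron double recording
#'
#' The neuron (pre-junctional) is held per the protocol; the non-neuronal
#' compartment sits at its own resting potential. With `g_gap > 0`,
#' hyperpolarizing steps into the neuron produce attenuated synchronized
#' deflections and a rebound in the non-neuronal trace.
#'
#' @inheritParams simulateCell
#' @param n_sweeps Sweep count recorded in the metadata (traces are
#'   noise-free averages unless `noise_sigma > 0`).
#' @return A [PairedTraces-class] object.
#' @examples
#' pr <- simulatePair(modelParams("long_rdp"),
#'                    stepProtocol(amp_pA = -200, t_total = 8))
#' @export
simulatePair <- function(params, protocol, drug = "control", fs = 20000,
                         cell_id = "pair", n_sweeps = 4) {
  stopifnot(is(params, "ModelParams"), is(protocol, "StepProtocol"))
  params <- applyDrug(params, drug)
  res <- .runModel(params, protocol, fs, 500)
  pmeta <- list(hold_mV = protocol@hold_mV, amp_pA = protocol@amp_pA,
                t_on = protocol@t_on, t_off = protocol@t_off,
                t_total = protocol@t_total, dt = protocol@dt)
  pre <- new("VoltageTrace", fs = fs, v_mV = res$vn, i_pA = res$i,
             meta = list(cell_id = cell_id, compartment = "neuron",
                         drug = drug, protocol = pmeta))
  post <- new("VoltageTrace", fs = fs, v_mV = res$vg,
              i_pA = rep(0, length(res$vg)),
              meta = list(cell_id = cell_id, compartment = "non_neuron",
                          drug = drug, protocol = pmeta))
  new("PairedTraces", pre = pre, post = post, n_sweeps = n_sweeps)
}

## ---------------------------------------------------------------------------
## cohorts and fixtures
## ---------------------------------------------------------------------------

# evaluate expr under a temporary RNG seed, restoring the caller's stream
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Generate a synthetic recording cohort
#'
#' Draws per-cell phenotypes (long vs short RDP, HF vs LF firing) as
#' independent Bernoulli variables from the seeded stream, then jitters the
#' key conductances of each cell lognormally around its phenotype preset.
#' Identical configurations give identical cohorts.
#'
#' @param config A [CohortConfig-class] object.
#' @return A list with `manifest` (data.frame: `cell_id`, `group`,
#'   `true_rdp`, `true_firing`) and `params` (list of [ModelParams-class],
#'   one per cell, each with its own noise seed).
#' @examples
#' co <- makeCohort(cohortConfig("naive", n_cells = 5, p_long = 0.4, seed = 1))
#' co$manifest
#' @export
makeCohort <- function(config) {
  stopifnot(is(config, "CohortConfig"))
  n <- as.integer(config@n_cells)
  .withSeed(as.integer(config@seed), {
    is_long <- runif(n) < config@p_long
    is_hf <- runif(n) < config@p_hf
    # excitability conductances take the full jitter; the coupling/plateau
    # machinery (glial T, CNG, gap) varies at half the spread so that the
    # labelled phenotype is realized reliably while plateau durations still
    # span a wide range
    jit_full <- c("g_T", "g_SK", "g_Na", "g_adapt", "g_leak_n")
    jit_half <- c("g_T_g", "g_CNG", "g_gap")
    params <- vector("list", n)
    for (i in seq_len(n)) {
      ph <- c(if (is_long[i]) "long_rdp" else "short_rdp",
              if (is_hf[i]) "hf" else "lf")
      p <- modelParams(ph)
      if (config@jitter_sd > 0) {
        v <- p@values
        v[jit_full] <- v[jit_full] *
          exp(rnorm(length(jit_full), 0, config@jitter_sd))
        v[jit_half] <- v[jit_half] *
          exp(rnorm(length(jit_half), 0, config@jitter_sd / 2))
        p <- new("ModelParams", values = v)
      }
      params[[i]] <- setParams(p, seed = as.integer(config@seed) * 1000 + i)
    }
    manifest <- data.frame(
      cell_id = sprintf("%s_%03d", config@group, seq_len(n)),
      group = config@group,
      true_rdp = ifelse(is_long, "long", "short"),
      true_firing = ifelse(is_hf, "hf", "lf"),
      stringsAsFactors = FALSE)
    list(manifest = manifest, params = params)
  })
}

#' Construct a synthetic ROI intensity table for dye-coupling analysis
#'
#' Builds per-ROI soma intensities and surround statistics (mean, SD) for
#' the neurobiotin (NB) and dextran-Alexa channels such that the intended
#' classes sit `margin` surround-SDs beyond the decision thresholds used by
#' [dyePositive()]: coupled cells are NB-positive and Alexa-negative,
#' uncoupled cells NB-negative, and double-positives NB- and
#' Alexa-positive. With `margin = 0` every constructed ROI lands exactly on
#' its threshold, where the strict-inequality convention classifies it as
#' negative (NB) or non-negative (Alexa).
#'
#' @param n_coupled,n_uncoupled,n_double_positive Class counts (>= 0).
#' @param seed Integer seed.
#' @param margin Distance from the decision boundary in surround-SD units.
#' @return data.frame with columns `roi_id`, `nb_mean`, `alexa_mean`,
#'   `nb_surround_mean`, `nb_surround_sd`, `alexa_surround_mean`,
#'   `alexa_surround_sd`, `is_recorded_cell`, `true_label`.
#' @examples
#' makeRoiFixture(3, 2, 1, seed = 1)
#' @export
makeRoiFixture <- function(n_coupled, n_uncoupled, n_double_positive, seed,
                           margin = 2) {
  stopifnot(n_coupled >= 0, n_uncoupled >= 0, n_double_positive >= 0)
  n <- n_coupled + n_uncoupled + n_double_positive
  cols <- c("roi_id", "nb_mean", "alexa_mean", "nb_surround_mean",
            "nb_surround_sd", "alexa_surround_mean", "alexa_surround_sd",
            "is_recorded_cell", "true_label")
  if (n == 0) {
    out <- data.frame(roi_id = character(), nb_mean = numeric(),
                      alexa_mean = numeric(), nb_surround_mean = numeric(),
                      nb_surround_sd = numeric(),
                      alexa_surround_mean = numeric(),
                      alexa_surround_sd = numeric(),
                      is_recorded_cell = logical(),
                      true_label = character(), stringsAsFactors = FALSE)
    return(out)
  }
  .withSeed(as.integer(seed), {
    lab <- c(rep("coupled", n_coupled), rep("uncoupled", n_uncoupled),
             rep("double_positive", n_double_positive))
    mu_nb <- runif(n, 90, 110); sd_nb <- runif(n, 8, 12)
    mu_ax <- runif(n, 90, 110); sd_ax <- runif(n, 8, 12)
    nb <- numeric(n); ax <- numeric(n)
    for (i in seq_len(n)) {
      if (lab[i] == "coupled") {
        nb[i] <- mu_nb[i] + (2 + margin) * sd_nb[i]
        ax[i] <- mu_ax[i] + (0.5 - margin) * sd_ax[i]
      } else if (lab[i] == "uncoupled") {
        nb[i] <- mu_nb[i] + (2 - margin) * sd_nb[i]
        ax[i] <- mu_ax[i] + (0.5 - margin) * sd_ax[i]
      } else {
        nb[i] <- mu_nb[i] + (2 + margin) * sd_nb[i]
        ax[i] <- mu_ax[i] + (0.5 + margin) * sd_ax[i]
      }
    }
    data.frame(roi_id = sprintf("roi_%03d", seq_len(n)), nb_mean = nb,
               alexa_mean = ax, nb_surround_mean = mu_nb,
               nb_surround_sd = sd_nb, alexa_surround_mean = mu_ax,
               alexa_surround_sd = sd_ax,
               is_recorded_cell = rep(FALSE, n), true_label = lab,
               stringsAsFactors = FALSE)
  })
}

#' Generate a synthetic feature-space cluster layout
#'
#' Draws labelled Gaussian clusters in (RDP duration, frequency adaptation
#' index) space. The default layout emulates the five clusters observed in
#' LHb cohorts: two short-RDP clusters (HF and LF), a long-RDP HF cluster
#' and two long-RDP LF clusters at increasing durations.
#'
#' @param n_per Points per cluster (scalar or vector).
#' @param seed Integer seed.
#' @param centers Matrix-like of cluster centres, columns `rdp_ms`, `fai`.
#' @param sds Matching matrix of per-axis SDs.
#' @return data.frame with `rdp_ms`, `fai`, `cluster` (integer label).
#' @examples
#' head(makeClusterLayout(20, seed = 1))
#' @export
makeClusterLayout <- function(n_per = 40, seed = 1,
                              centers = cbind(rdp_ms = c(150, 210, 1200, 2500, 6000),
                                              fai = c(0.35, 0.95, 0.45, 0.90, 0.98)),
                              sds = cbind(rdp_ms = c(40, 50, 180, 250, 350),
                                          fai = c(0.06, 0.025, 0.06, 0.02, 0.008))) {
  centers <- as.matrix(centers); sds <- as.matrix(sds)
  k <- nrow(centers)
  if (length(n_per) == 1) n_per <- rep(n_per, k)
  stopifnot(length(n_per) == k, nrow(sds) == k)
  .withSeed(as.integer(seed), {
    out <- do.call(rbind, lapply(seq_len(k), function(j) {
      data.frame(rdp_ms = rnorm(n_per[j], centers[j, 1], sds[j, 1]),
                 fai = rnorm(n_per[j], centers[j, 2], sds[j, 2]),
                 cluster = j)
    }))
    out$rdp_ms <- pmax(out$rdp_ms, 1)
    out$fai <- pmin(pmax(out$fai, 0), 1)
    out
  })
}
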