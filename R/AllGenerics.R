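#' @include AllClasses.R
NULL

#' Read a single model parameter
#'
#' @param object A [ModelParams-class] object.
#' @param name Parameter name (see [modelParams()] for the dictionary).
#' @return Numeric scalar.
#' @examples
#' param(modelParams("long_rdp"), "g_CNG")
#' @export
setGeneric("param", function(object, name) standardGeneric("param"))

#' @rdname param
#' @export
setMethod("param", "ModelParams", function(object, name) {
  if (!name %in% names(object@values))
    stop("unknown model parameter: ", name)
  unname(object@values[name])
})

#' Replace model parameters, returning a new object
#'
#' @param object A [ModelParams-class] object.
#' @param ... Named numeric scalars to replace.
#' @return A new, validated [ModelParams-class]; the input is untouched.
#' @examples
#' p <- setParams(modelParams("long_rdp"), g_gap = 0)
#' @export
setGeneric("setParams", function(object, ...) standardGeneric("setParams"))

#' @rdname setParams
#' @export
setMethod("setParams", "ModelParams", function(object, ...) {
  upd <- c(...)
  if (length(upd) == 0) return(object)
  bad <- setdiff(names(upd), names(object@values))
  if (length(bad)) stop("unknown model parameter(s): ", paste(bad, collapse = ", "))
  v <- object@values
  v[names(upd)] <- upd
  new("ModelParams", values = v)
})

#' Accessors for voltage traces
#'
#' `voltage()`, `injectedCurrent()`, `samplingRate()`, `traceTime()` and
#' `traceMeta()` read the sample vectors, sampling rate (Hz), time base (s)
#' and metadata of a [VoltageTrace-class].
#'
#' @param object A [VoltageTrace-class] object.
#' @return Numeric vector (`voltage`, `injectedCurrent`, `traceTime`),
#'   scalar (`samplingRate`) or list (`traceMeta`).
#' @name trace-accessors
NULL

#' @rdname trace-accessors
#' @export
setGeneric("voltage", function(object) standardGeneric("voltage"))
#' @rdname trace-accessors
#' @export
setMethod("voltage", "VoltageTrace", function(object) object@v_mV)

#' @rdname trace-accessors
#' @export
setGeneric("injectedCurrent", function(object) standardGeneric("injectedCurrent"))
#' @rdname trace-accessors
#' @export
setMethod("injectedCurrent", "VoltageTrace", function(object) object@i_pA)

#' @rdname trace-accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))
#' @rdname trace-accessors
#' @export
setMethod("samplingRate", "VoltageTrace", function(object) object@fs)

#' @rdname trace-accessors
#' @export
setGeneric("traceTime", function(object) standardGeneric("traceTime"))
#' @rdname trace-accessors
#' @export
setMethod("traceTime", "VoltageTrace", function(object)
  (seq_along(object@v_mV) - 1) / object@fs)

#' @rdname trace-accessors
#' @export
setGeneric("traceMeta", function(object) standardGeneric("traceMeta"))
#' @rdname trace-accessors
#' @export
setMethod("traceMeta", "VoltageTrace", function(object) object@meta)

#' Accessors for paired recordings
#'
#' @param object A [PairedTraces-class] object.
#' @return The pre- or post-junctional [VoltageTrace-class].
#' @name pair-accessors
NULL

#' @rdname pair-accessors
#' @export
setGeneric("preTrace", function(object) standardGeneric("preTrace"))
#' @rdname pair-accessors
#' @export
setMethod("preTrace", "PairedTraces", function(object) object@pre)

#' @rdname pair-accessors
#' @export
setGeneric("postTrace", function(object) standardGeneric("postTrace"))
#' @rdname pair-accessors
#' @export
setMethod("postTrace", "PairedTraces", function(object) object@post)

setMethod("show", "ModelParams", function(object) {
  v <- object@values
  cat("ModelParams (two-compartment neuron/glia model)\n")
  cat(sprintf("  neuron: C=%.1f pF, g_leak=%.2f nS (E=%.1f mV), g_Na=%.0f, g_K=%.0f, g_T=%.1f, g_SK=%.1f, g_H=%.1f, g_adapt=%.1f nS\n",
              v["C_n"], v["g_leak_n"], v["E_leak_n"], v["g_Na"], v["g_K"],
              v["g_T"], v["g_SK"], v["g_H"], v["g_adapt"]))
  cat(sprintf("  glia:   C=%.1f pF, g_leak=%.2f nS (E=%.1f mV), g_T_g=%.1f, g_CNG=%.1f nS (theta=%.1f mV, alpha=%.2f/s, beta=%.3f/s)\n",
              v["C_g"], v["g_leak_g"], v["E_leak_g"], v["g_T_g"], v["g_CNG"],
              v["theta_CNG"], v["alpha"], v["beta"]))
  cat(sprintf("  coupling: g_gap=%.2f nS; noise_sigma=%.1f pA; seed=%d\n",
              v["g_gap"], v["noise_sigma"], as.integer(v["seed"])))
  invisible(object)
})

setMethod("show", "StepProtocol", function(object) {
  hold <- if (is.na(object@hold_mV)) "rest" else sprintf("%.0f mV", object@hold_mV)
  cat(sprintf("StepProtocol: hold %s, %+.0f pA step %.2f-%.2f s, total %.2f s, dt %.3f ms\n",
              hold, object@amp_pA, object@t_on, object@t_off,
              object@t_total, object@dt))
  invisible(object)
})

setMethod("show", "VoltageTrace", function(object) {
  m <- object@meta
  cat(sprintf("VoltageTrace: %d samples @ %.0f Hz (%.2f s), compartment=%s\n",
              length(object@v_mV), object@fs,
              length(object@v_mV) / object@fs,
              if (is.null(m$compartment)) "?" else m$compartment))
  cat(sprintf("  V range [%.1f, %.1f] mV; cell=%s drug=%s\n",
              min(object@v_mV), max(object@v_mV),
              if (is.null(m$cell_id)) "?" else m$cell_id,
              if (is.null(m$drug)) "?" else m$drug))
  invisible(object)
})

setMethod("show", "PairedTraces", function(object) {
  cat(sprintf("PairedTraces: %d samples @ %.0f Hz, %d sweep(s) averaged\n",
              length(object@pre@v_mV), object@pre@fs, object@n_sweeps))
  invisible(object)
})

setMethod("show", "CohortConfig", function(object) {
  cat(sprintf("CohortConfig '%s': n=%d, p_long=%.2f, p_hf=%.2f, jitter_sd=%.2f, seed=%d\n",
              object@group, as.integer(object@n_cells), object@p_long,
              object@p_hf, object@jitter_sd, as.integer(object@seed)))
  invisible(object)
})
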