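#' @include coupling.R classify.R stats.R
#' @importFrom data.table fwrite fread
#' @importFrom jsonlite write_json read_json toJSON
#' @importFrom utils packageVersion
NULL

## On-disk formats (CSV trace + JSON sidecar) and end-to-end pipeline
## orchestration: simulate -> features -> classify -> cohort statistics.

#' Write a voltage trace as CSV with a JSON sidecar
#'
#' The CSV carries `time_s`, `v_mV`, `i_pA` at full (round-trip) numeric
#' precision; the sidecar (`<path>.json` with the `.csv` stripped) carries
#' the sampling rate and metadata.
#'
#' @param trace A [VoltageTrace-class].
#' @param path Output CSV path (`.csv`).
#' @return Invisibly, the sidecar path.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeTrace(voltageTrace(rep(-60, 100), fs = 1000), f)
#' @export
writeTrace <- function(trace, path) {
  stopifnot(is(trace, "VoltageTrace"))
  if (!grepl("\\.csv$", path)) stop("trace path must end in .csv")
  # %.17g strings guarantee bit-exact numeric round-trip through fread
  dt <- data.frame(time_s = formatC(traceTime(trace), format = "g", digits = 17),
                   v_mV = formatC(trace@v_mV, format = "g", digits = 17),
                   i_pA = formatC(trace@i_pA, format = "g", digits = 17))
  fwrite(dt, path, quote = FALSE)
  sidecar <- sub("\\.csv$", ".json", path)
  meta <- trace@meta
  write_json(list(fs = trace@fs, n_samples = length(trace@v_mV),
                  meta = meta),
             sidecar, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(sidecar)
}

#' Read a voltage trace written by [writeTrace()]
#'
#' Requires the JSON sidecar and a uniform time base (tolerance 1e-9 s);
#' a gap in the time column is rejected with the offending line number.
#'
#' @param path CSV path.
#' @return A [VoltageTrace-class].
#' @export
readTrace <- function(path) {
  sidecar <- sub("\\.csv$", ".json", path)
  if (!file.exists(sidecar))
    stop("missing JSON sidecar: ", sidecar)
  side <- read_json(sidecar, simplifyVector = TRUE)
  dt <- fread(path, colClasses = "numeric", showProgress = FALSE)
  need <- c("time_s", "v_mV", "i_pA")
  if (!all(need %in% names(dt)))
    stop("trace CSV must have columns time_s, v_mV, i_pA")
  tt <- dt$time_s
  step <- 1 / side$fs
  bad <- which(abs(diff(tt) - step) > 1e-9)
  if (length(bad))
    stop(sprintf("non-uniform time base at line %d (gap %.3g s, expected %.3g s)",
                 bad[1] + 2L, diff(tt)[bad[1]], step))
  meta <- side$meta
  if (is.null(meta)) meta <- list()
  new("VoltageTrace", fs = as.numeric(side$fs), v_mV = dt$v_mV,
      i_pA = dt$i_pA, meta = meta)
}

#' Extract classification features for a whole cohort
#'
#' Runs [cellFeatures()] for every cell of a generated cohort and binds
#' the results to the cohort manifest.
#'
#' @param cohort Result of [makeCohort()].
#' @param ... Passed to [cellFeatures()] (protocols, sampling rate).
#' @return data.frame: manifest columns plus the feature columns.
#' @export
cohortFeatures <- function(cohort, ...) {
  stopifnot(is.list(cohort), !is.null(cohort$manifest), !is.null(cohort$params))
  n <- nrow(cohort$manifest)
  if (n == 0) stop("empty cohort")
  feats <- do.call(rbind, lapply(seq_len(n), function(i)
    cellFeatures(cohort$params[[i]], ...)))
  cbind(cohort$manifest, feats)
}

#' Run the full cohort analysis pipeline
#'
#' Simulates the configured cohorts, extracts the classification features
#' (RDP duration at -100 pA, frequency adaptation index at +100 pA), fits
#' the VB-GMM, derives (or accepts) the subtype thresholds, assigns
#' subtype labels, tabulates group-by-class counts and runs the
#' chi-squared/residual comparison. All outputs are deterministic given
#' the seeds in `config`; a provenance log records the configuration and
#' seeds needed to reproduce every file.
#'
#' @param config List with elements:
#'   \describe{
#'     \item{groups}{list of lists with `group`, `n_cells`, `p_long`, and
#'       optionally `p_hf`, `jitter_sd`;}
#'     \item{seed}{integer master seed (per-group seeds are derived);}
#'     \item{out_dir}{output directory (created); omit for no files;}
#'     \item{thresholds}{optional fixed thresholds list, skipping the fit;}
#'     \item{rdp_protocol, depol_protocol}{optional protocol overrides;}
#'     \item{fs}{sampling rate, default 20000.}
#'   }
#' @return List: `features` (data.frame), `labels` (data.frame),
#'   `thresholds`, `model` (or `NULL` if fixed thresholds were given),
#'   `rdp_table` (group x RDP class counts), `stats`
#'   (chi-squared + residuals on `rdp_table`), `provenance`.
#' @examples
#' \donttest{
#' cfg <- list(groups = list(list(group = "a", n_cells = 6, p_long = 0.5)),
#'             seed = 1)
#' res <- runPipeline(cfg)
#' }
#' @export
runPipeline <- function(config) {
  if (is.null(config$groups) || length(config$groups) == 0)
    stop("pipeline config has no cohort groups")
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  fs <- if (is.null(config$fs)) 20000 else config$fs
  rdp_protocol <- if (is.null(config$rdp_protocol)) stepProtocol(amp_pA = -100)
                  else config$rdp_protocol
  depol_protocol <- if (is.null(config$depol_protocol))
                      stepProtocol(amp_pA = 100, t_total = 2.5)
                    else config$depol_protocol

  features <- NULL
  for (gi in seq_along(config$groups)) {
    g <- config$groups[[gi]]
    if (is.null(g$n_cells) || g$n_cells < 1)
      stop("empty cohort in group ", gi)
    cc <- cohortConfig(group = g$group, n_cells = g$n_cells,
                       p_long = g$p_long,
                       p_hf = if (is.null(g$p_hf)) 0.6 else g$p_hf,
                       jitter_sd = if (is.null(g$jitter_sd)) 0.1
                                   else g$jitter_sd,
                       seed = seed * 100L + gi)
    co <- makeCohort(cc)
    fe <- tryCatch(
      cohortFeatures(co, rdp_protocol = rdp_protocol,
                     depol_protocol = depol_protocol, fs = fs),
      error = function(e) stop("feature extraction failed in group '",
                               g$group, "': ", conditionMessage(e)))
    features <- rbind(features, fe)
  }

  model <- NULL
  if (!is.null(config$thresholds)) {
    thresholds <- config$thresholds
  } else {
    ok <- is.finite(features$rdp_ms) & is.finite(features$fai)
    model <- fitVbgmm(features[ok, c("rdp_ms", "fai")], seed = seed)
    thresholds <- deriveThresholds(model)
    if (!thresholds$defined)
      stop("threshold derivation failed: single effective component")
  }
  labels <- assignSubtype(features, thresholds)

  rdp_table <- table(labels$group, labels$rdp_class)
  stats <- if (nrow(rdp_table) >= 2 && ncol(rdp_table) >= 2)
    chiSquaredResiduals(unclass(rdp_table)) else NULL

  provenance <- list(package_version = as.character(packageVersion("lhbRDP")),
                     seed = seed,
                     groups = config$groups,
                     fs = fs,
                     thresholds_fixed = !is.null(config$thresholds))

  out <- list(features = features, labels = labels,
              thresholds = thresholds, model = model,
              rdp_table = rdp_table, stats = stats,
              provenance = provenance)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    fwrite(features, file.path(config$out_dir, "features.csv"))
    fwrite(labels, file.path(config$out_dir, "labels.csv"))
    write_json(thresholds, file.path(config$out_dir, "thresholds.json"),
               auto_unbox = TRUE, digits = NA)
    if (!is.null(stats))
      write_json(list(statistic = stats$statistic, df = stats$df,
                      p.value = stats$p.value,
                      residuals = stats$residuals,
                      residual_p = stats$residual_p,
                      direction = stats$direction),
                 file.path(config$out_dir, "stats.json"),
                 auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
    write_json(provenance, file.path(config$out_dir, "provenance.json"),
               auto_unbox = TRUE, digits = NA)
  }
  out
}
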