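#' @include features.R
#' @importFrom stats cor wilcox.test median
NULL

## Paired-recording synchrony and dye-coupling quantification.

#' Spearman synchrony of a neuron / non-neuron pair
#'
#' Spearman rank correlation between the pre- and post-junctional voltage
#' traces over the analysis window (step onset to `post_s` seconds after
#' offset). Traces are low-pass filtered first (unless `filter = FALSE`,
#' for already-preprocessed sweep averages). The pair is flagged coupled
#' when rho exceeds `rho_min`.
#'
#' @param pair A [PairedTraces-class] object.
#' @param protocol The [StepProtocol-class] of the injected step; taken
#'   from the trace metadata when omitted.
#' @param post_s Length of the post-offset window included (s).
#' @param rho_min Coupling flag threshold on rho.
#' @param filter Apply [lowpass10Hz()] to both traces first.
#' @return List: `rho`, `coupled`.
#' @examples
#' pr <- stepProtocol(amp_pA = -200, t_total = 6)
#' synchrony(simulatePair(modelParams("long_rdp"), pr), pr)$rho
#' @export
synchrony <- function(pair, protocol = NULL, post_s = 3, rho_min = 0.5,
                      filter = TRUE) {
  stopifnot(is(pair, "PairedTraces"))
  pre <- pair@pre; post <- pair@post
  if (is.null(protocol)) {
    pm <- pre@meta$protocol
    if (is.null(pm)) stop("no protocol supplied and none in the metadata")
    protocol <- stepProtocol(hold_mV = pm$hold_mV, amp_pA = pm$amp_pA,
                             t_on = pm$t_on, t_off = pm$t_off,
                             t_total = pm$t_total, dt = pm$dt)
  }
  fs <- pre@fs
  v1 <- if (filter) lowpass10Hz(pre)@v_mV else pre@v_mV
  v2 <- if (filter) lowpass10Hz(post)@v_mV else post@v_mV
  i0 <- .idx(protocol@t_on, fs)
  i1 <- min(length(v1), .idx(protocol@t_off + post_s, fs))
  rho <- suppressWarnings(cor(v1[i0:i1], v2[i0:i1], method = "spearman"))
  list(rho = rho, coupled = is.finite(rho) && rho > rho_min)
}

#' Rebound-to-hyperpolarization amplitude ratio
#'
#' Peak post-offset depolarizing deflection above baseline divided by the
#' peak hyperpolarizing deflection magnitude during the step, both on the
#' filtered trace; 0 when no rebound rises above baseline. In coupled
#' pairs this ratio is larger post-junctionally, consistent with the
#' rebound being generated mainly in the non-neuronal compartment.
#'
#' @param trace A [VoltageTrace-class] from a hyperpolarizing step.
#' @param protocol The matching [StepProtocol-class].
#' @param filter Apply [lowpass10Hz()] first.
#' @return Numeric ratio (>= 0).
#' @export
amplitudeRatio <- function(trace, protocol, filter = TRUE) {
  stopifnot(is(trace, "VoltageTrace"), is(protocol, "StepProtocol"))
  if (protocol@amp_pA >= 0)
    stop("amplitude ratio requires a hyperpolarizing step")
  fs <- trace@fs
  v <- if (filter) lowpass10Hz(trace)@v_mV else trace@v_mV
  bw <- .baselineWindow(trace, protocol)
  baseline <- mean(v[bw[1]:bw[2]])
  i_on <- .idx(protocol@t_on, fs); i_off <- .idx(protocol@t_off, fs) - 1L
  hyp <- max(baseline - v[i_on:i_off])
  if (hyp <= 0) stop("no hyperpolarizing deflection during the step")
  reb <- max(v[(i_off + 1L):length(v)] - baseline)
  if (reb <= 0) return(0)
  reb / hyp
}

#' Dye-coupling positivity criteria for ROI intensities
#'
#' A cell is neurobiotin (NB) positive iff its soma mean intensity exceeds
#' the surround mean plus two surround SDs; it is dextran-Alexa negative
#' iff its soma mean is below the surround mean plus half a surround SD
#' (strict inequalities). A coupled cell is NB-positive, Alexa-negative
#' and not the recorded cell; NB- and Alexa-double-positive cells are
#' excluded as spillover artefacts.
#'
#' @param roi data.frame with columns `nb_mean`, `alexa_mean`,
#'   `nb_surround_mean`, `nb_surround_sd`, `alexa_surround_mean`,
#'   `alexa_surround_sd`, `is_recorded_cell` (see [makeRoiFixture()]).
#' @return data.frame: `roi` columns plus logical `nb_positive`,
#'   `alexa_negative`, `coupled`, `excluded`.
#' @examples
#' dyePositive(makeRoiFixture(2, 1, 1, seed = 1))
#' @export
dyePositive <- function(roi) {
  need <- c("nb_mean", "alexa_mean", "nb_surround_mean", "nb_surround_sd",
            "alexa_surround_mean", "alexa_surround_sd", "is_recorded_cell")
  miss <- setdiff(need, names(roi))
  if (length(miss))
    stop("missing ROI channel column(s): ", paste(miss, collapse = ", "))
  nb_positive <- roi$nb_mean > roi$nb_surround_mean + 2 * roi$nb_surround_sd
  alexa_negative <- roi$alexa_mean <
    roi$alexa_surround_mean + 0.5 * roi$alexa_surround_sd
  coupled <- nb_positive & alexa_negative & !roi$is_recorded_cell
  excluded <- nb_positive & !alexa_negative
  cbind(roi, nb_positive = nb_positive, alexa_negative = alexa_negative,
        coupled = coupled, excluded = excluded)
}

#' Summarise dye coupling across recordings
#'
#' Accepts either a list of per-recording ROI tables (each run through
#' [dyePositive()]) or a numeric vector of per-recording coupled-cell
#' counts. Reports the per-recording counts, the incidence (percentage of
#' recordings with at least one coupled cell), optional marker-positive
#' fractions among coupled cells, and, when a two-level `condition` is
#' given, a two-sided Mann-Whitney U comparison of the per-recording
#' counts between conditions.
#'
#' @param recordings List of ROI data.frames, or numeric vector of
#'   per-recording coupled-cell counts.
#' @param markers Character vector of logical marker columns to summarise
#'   among coupled cells (e.g. `c("neun", "olig2", "pgdh")`); list input
#'   only.
#' @param condition Optional factor (one level per recording) for the
#'   Mann-Whitney comparison.
#' @return List: `n_recordings`, `coupled_counts`, `n_with_coupling`,
#'   `incidence_pct`, `marker_pct` (named vector, `NULL` if no markers),
#'   `marker_counts`, `test` (`NULL` unless `condition` given).
#' @examples
#' couplingSummary(c(rep(1, 19), rep(0, 3)))$incidence_pct
#' @export
couplingSummary <- function(recordings, markers = NULL, condition = NULL) {
  if (is.numeric(recordings)) {
    counts <- recordings
    marker_pct <- NULL
    marker_counts <- NULL
    if (!is.null(markers))
      stop("marker summaries need per-ROI tables, not counts")
  } else if (is.list(recordings) && length(recordings) > 0) {
    scored <- lapply(recordings, dyePositive)
    counts <- vapply(scored, function(d) sum(d$coupled), numeric(1))
    marker_pct <- NULL
    marker_counts <- NULL
    if (!is.null(markers)) {
      pooled <- do.call(rbind, lapply(scored, function(d)
        d[d$coupled, , drop = FALSE]))
      marker_counts <- vapply(markers, function(mk) {
        if (!mk %in% names(pooled)) stop("missing marker column: ", mk)
        c(sum(pooled[[mk]], na.rm = TRUE), sum(!is.na(pooled[[mk]])))
      }, numeric(2))
      marker_pct <- 100 * marker_counts[1, ] / marker_counts[2, ]
      names(marker_pct) <- markers
    }
  } else {
    stop("empty input: supply ROI tables or per-recording counts")
  }
  test <- NULL
  if (!is.null(condition)) {
    condition <- factor(condition)
    if (nlevels(condition) != 2 || length(condition) != length(counts))
      stop("condition must be a two-level factor, one value per recording")
    wt <- suppressWarnings(wilcox.test(counts ~ condition, exact = FALSE))
    test <- list(test = "mann_whitney_u", statistic = unname(wt$statistic),
                 p.value = wt$p.value)
  }
  list(n_recordings = length(counts), coupled_counts = counts,
       n_with_coupling = sum(counts >= 1),
       incidence_pct = 100 * mean(counts >= 1),
       marker_pct = marker_pct, marker_counts = marker_counts,
       test = test)
}

#' Marker-positive percentage among coupled cells
#'
#' @param n_positive Marker-positive coupled cells.
#' @param n_total Coupled cells tested for the marker.
#' @return Percentage (0-100).
#' @examples
#' markerFraction(7, 37)
#' @export
markerFraction <- function(n_positive, n_total) {
  if (n_total < 1 || n_positive < 0 || n_positive > n_total)
    stop("need 0 <= n_positive <= n_total with n_total >= 1")
  100 * n_positive / n_total
}

#' Reference tallies from the LHb dye-coupling and double-recording study
#'
#' Printed count data from the whole-cell dye-filling and paired-recording
#' experiments in mouse LHb slices that this package's analyses model:
#' dye-coupling incidence under control and carbenoxolone, marker
#' identities of coupled cells (NeuN for neurons, Olig2 for
#' oligodendrocyte-lineage cells, 3PGDH for astrocytes), and the tally of
#' synchronized neuron/non-neuron double recordings. Feed these counts to
#' [couplingSummary()] / [markerFraction()] to recompute the published
#' percentages.
#'
#' @return Nested list: `dye_coupling$control` and
#'   `dye_coupling$carbenoxolone` (`n_recordings`, `n_with_coupling`),
#'   `markers` (rows `n_positive`, `n_total` for neun/olig2/pgdh),
#'   `paired_recordings` (`n_pairs`, `n_synchronized`, and the
#'   neuron-neuron pair tally).
#' @examples
#' tl <- lhbReferenceTallies()
#' with(tl$dye_coupling$control,
#'      couplingSummary(c(rep(1, n_with_coupling),
#'                        rep(0, n_recordings - n_with_coupling))))$incidence_pct
#' @export
lhbReferenceTallies <- function() {
  list(
    dye_coupling = list(
      control = list(n_recordings = 22, n_with_coupling = 19),
      carbenoxolone = list(n_recordings = 7, n_with_coupling = 4)),
    markers = list(neun = c(n_positive = 7, n_total = 37),
                   olig2 = c(n_positive = 14, n_total = 26),
                   pgdh = c(n_positive = 0, n_total = 45)),
    paired_recordings = list(
      neuron_non_neuron = list(n_pairs = 13, n_synchronized = 5),
      neuron_neuron = list(n_pairs = 18, n_synchronized = 0)))
}
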