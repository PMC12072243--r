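#' @include vbgmm.R
NULL

## Firing-subtype classification: thresholds on (RDP duration, frequency
## adaptation index) derived from the mixture fit, four-way subtype labels,
## and behavioural phenotyping of chronically stressed mice.

# largest-gap grouping of effective component means along one axis;
# durations are compared on a log10 scale (they span orders of magnitude),
# the threshold itself is the arithmetic midpoint of the two flanking means
.axisThreshold <- function(mu, log_scale = FALSE) {
  mu <- sort(unique(mu))
  if (length(mu) < 2) return(NA_real_)
  sp <- if (log_scale) log10(mu + 1) else mu
  gaps <- diff(sp)
  j <- which.max(gaps)
  (mu[j] + mu[j + 1]) / 2
}

#' Derive classification thresholds from a fitted mixture
#'
#' Effective mixture components are merged into low/high groups along each
#' feature axis at the largest gap between component means (the RDP axis is
#' inspected on a log scale because durations span orders of magnitude),
#' and each threshold is the midpoint between the two nearest opposing
#' component means. With a single effective component no boundary exists
#' and the thresholds are flagged undefined.
#'
#' @param model A `"vbgmm"` fit from [fitVbgmm()].
#' @return List: `theta_rdp_ms`, `theta_fai`, `defined`.
#' @examples
#' fit <- fitVbgmm(makeClusterLayout(15, seed = 1)[, 1:2], seed = 1)
#' deriveThresholds(fit)
#' @export
deriveThresholds <- function(model) {
  stopifnot(inherits(model, "vbgmm"))
  mu <- model$means[model$effective, , drop = FALSE]
  if (nrow(mu) < 2)
    return(list(theta_rdp_ms = NA_real_, theta_fai = NA_real_,
                defined = FALSE))
  th_rdp <- .axisThreshold(mu[, 1], log_scale = TRUE)
  th_fai <- .axisThreshold(mu[, 2], log_scale = FALSE)
  list(theta_rdp_ms = th_rdp, theta_fai = th_fai,
       defined = is.finite(th_rdp) && is.finite(th_fai))
}

#' Assign RDP and firing subtypes from thresholds
#'
#' A cell is short-RDP iff its RDP duration is strictly below
#' `theta_rdp_ms` (the boundary cell is long), and HF-firing iff its
#' frequency adaptation index is less than or equal to `theta_fai` (the
#' boundary cell is HF). Cells with an undefined adaptation index keep
#' their RDP class but get `NA` firing and combined labels, so they drop
#' out of four-way tables while remaining in two-way RDP tables.
#'
#' @param features data.frame with columns `rdp_ms` and `fai`.
#' @param thresholds List with `theta_rdp_ms` and `theta_fai`, e.g. from
#'   [deriveThresholds()] or `list(theta_rdp_ms = 400, theta_fai = 0.8)`.
#' @return data.frame: input columns plus `rdp_class` (`"short"|"long"`),
#'   `firing_class` (`"HF"|"LF"` or `NA`), `combined` (e.g. `"short&HF"`).
#' @examples
#' assignSubtype(data.frame(rdp_ms = c(200, 2500, 400), fai = c(0.5, 0.9, 0.8)),
#'               list(theta_rdp_ms = 400, theta_fai = 0.8))
#' @export
assignSubtype <- function(features, thresholds) {
  stopifnot(all(c("rdp_ms", "fai") %in% names(features)))
  if (!is.finite(thresholds$theta_rdp_ms) ||
      !is.finite(thresholds$theta_fai))
    stop("thresholds are undefined; refit or supply fixed values")
  rdp_class <- ifelse(features$rdp_ms < thresholds$theta_rdp_ms,
                      "short", "long")
  firing_class <- ifelse(is.na(features$fai), NA_character_,
                         ifelse(features$fai <= thresholds$theta_fai,
                                "HF", "LF"))
  combined <- ifelse(is.na(firing_class), NA_character_,
                     paste0(rdp_class, "&", firing_class))
  cbind(features, rdp_class = rdp_class, firing_class = firing_class,
        combined = combined, stringsAsFactors = FALSE)
}

#' Classify mice from the social avoidance test
#'
#' A mouse is susceptible if its interaction ratio is below 1 AND its
#' interaction time with the unfamiliar aggressor is below 40 s; otherwise
#' it is resilient if the ratio exceeds 1 OR the interaction time exceeds
#' 60 s; remaining mice are intermediate.
#'
#' @param interaction_time_s Interaction time with the aggressor (s).
#' @param interaction_ratio Interaction time ratio
#'   (aggressor present / empty enclosure).
#' @return Character vector: `"susceptible"`, `"resilient"` or
#'   `"intermediate"`.
#' @examples
#' phenotypeMouse(c(3, 66, 40.5), c(0.06, 1.10, 0.96))
#' @export
phenotypeMouse <- function(interaction_time_s, interaction_ratio) {
  if (length(interaction_time_s) != length(interaction_ratio))
    stop("inputs must have equal length")
  if (any(!is.finite(interaction_time_s)) || any(!is.finite(interaction_ratio)))
    stop("inputs must be finite")
  if (any(interaction_time_s < 0) || any(interaction_ratio < 0))
    stop("interaction times and ratios must be non-negative")
  ifelse(interaction_ratio < 1 & interaction_time_s < 40, "susceptible",
         ifelse(interaction_ratio > 1 | interaction_time_s > 60,
                "resilient", "intermediate"))
}

#' Social avoidance test results of the chronically defeated cohort
#'
#' Interaction times (s) and interaction ratios of the 19 chronically
#' defeated mice whose LHb neurons this package's cohort analyses model,
#' together with their published phenotype calls. [phenotypeMouse()]
#' applied to the two measures reproduces the `phenotype` column.
#'
#' @return data.frame: `mouse_id`, `interaction_time_s`,
#'   `interaction_ratio`, `phenotype`.
#' @examples
#' tab <- socialAvoidanceTable()
#' all(phenotypeMouse(tab$interaction_time_s, tab$interaction_ratio) ==
#'     tab$phenotype)
#' @export
socialAvoidanceTable <- function() {
  data.frame(
    mouse_id = sprintf("Mouse %03d", 1:19),
    interaction_time_s = c(3, 15, 22, 13, 4, 18.5, 66, 71, 21.5, 73, 28.5,
                           40.5, 9.5, 42, 10, 64, 63.5, 24, 58.5),
    interaction_ratio = c(0.06, 0.24, 0.43, 0.22, 0.07, 0.31, 1.10, 1.28,
                          0.28, 0.74, 2.38, 0.96, 0.28, 3.00, 0.42, 0.79,
                          0.69, 1.66, 1.18),
    phenotype = c("susceptible", "susceptible", "susceptible", "susceptible",
                  "susceptible", "susceptible", "resilient", "resilient",
                  "susceptible", "resilient", "resilient", "intermediate",
                  "susceptible", "resilient", "susceptible", "resilient",
                  "resilient", "resilient", "resilient"),
    stringsAsFactors = FALSE)
}
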