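## Lick-behavior summaries and the geometric social-interaction rule.

trialsOfType <- function(trials, trialType) {
  sel <- trials[trials$type %in% trialType, , drop = FALSE]
  if (!nrow(sel))
    stopf("no trials of type '%s'", paste(trialType, collapse = "/"))
  sel
}

#' Peri-stimulus time histogram of lick probability
#'
#' Per-bin lick probability around CS onset: the fraction of trials of the
#' requested type with at least one lick inside the bin (probability of
#' licking, not a lick-count rate). Bins are half-open `[t, t + binWidth)`
#' relative to CS onset and tile the requested window, which must span CS
#' onset.
#'
#' @param licks Numeric lick timestamps (s, session clock).
#' @param trials Trial table with `type` and `cs_onset_s` columns.
#' @param trialType Trial type(s) to include (default `"reward"`).
#' @param binWidth Bin width (s).
#' @param window `(start, end)` window relative to CS onset (s).
#' @return Data frame with `bin_start`, `bin_end`, `lick_probability`
#'   columns and an `n_trials` attribute.
#' @export
lickPSTH <- function(licks, trials, trialType = "reward", binWidth = 0.25,
                     window = c(-2, 8)) {
  if (binWidth <= 0) stopf("binWidth must be > 0")
  if (window[1] >= 0 || window[2] <= 0)
    stopf("window must span CS onset")
  sel <- trialsOfType(trials, trialType)
  edges <- seq(window[1], window[2], by = binWidth)
  nb <- length(edges) - 1L
  hit <- matrix(FALSE, nrow(sel), nb)
  for (i in seq_len(nrow(sel))) {
    rel <- licks - sel$cs_onset_s[i]
    rel <- rel[rel >= window[1] & rel < window[2]]
    if (length(rel))
      hit[i, unique(pmin(nb, floor((rel - window[1]) / binWidth) + 1L))] <- TRUE
  }
  out <- data.frame(bin_start = edges[-length(edges)], bin_end = edges[-1],
                    lick_probability = colMeans(hit))
  attr(out, "n_trials") <- nrow(sel)
  out
}

#' Lick probability in a peri-CS window
#'
#' Fraction of trials of the requested type with at least one lick inside
#' the half-open window `[from, to)` relative to CS onset. The default
#' windows of interest are anticipatory (0, 2) s (CS onset to US delivery)
#' and consummatory (2, 5) s (US delivery to CS offset).
#'
#' @inheritParams lickPSTH
#' @param window `(from, to)` relative to CS onset (s).
#' @return Fraction in \[0, 1\].
#' @export
windowLickProbability <- function(licks, trials, window = c(0, 2),
                                  trialType = "reward") {
  if (window[1] >= window[2]) stopf("window must satisfy from < to")
  sel <- trialsOfType(trials, trialType)
  if (!length(licks)) return(0)
  hits <- vapply(sel$cs_onset_s, function(cs) {
    any(licks - cs >= window[1] & licks - cs < window[2])
  }, logical(1))
  mean(hits)
}

#' Pearson correlation with two-sided p-value
#'
#' Thin wrapper around [stats::cor.test()] for per-mouse scalar pairs
#' (e.g. lick probability vs sucrose preference), with the argument checks
#' the pipeline relies on.
#'
#' @param x,y Numeric vectors of equal length (n >= 3), finite.
#' @return List with elements `r` and `p`.
#' @export
pearsonCorrelation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stopf("need >= 3 paired observations")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stopf("values must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stopf("undefined correlation: zero variance")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Geometric social-interaction scoring
#'
#' Counts a frame as interacting with a cup when the nose is within
#' `radiusFactor` (default 1.3) times the cup radius of the cup center AND
#' the animal is facing the cup: the angle between the body-to-nose
#' direction and the nose-to-cup direction is at most `angleMaxDeg`
#' (default 90 degrees). The angle vertex sits at the nose by default
#' (`vertex = "nose"`); `vertex = "body"` instead thresholds the angle at
#' the body between the body-to-nose and body-to-cup directions. Frames
#' with missing nose or body coordinates are skipped and counted.
#'
#' The social index is social time / (social time + nonsocial time).
#'
#' @param frames Data frame with per-frame `nose_x`, `nose_y`, `body_x`,
#'   `body_y` columns (px).
#' @param cups Data frame with columns `cup` (containing `"social"` and
#'   `"nonsocial"`), `x`, `y`, `radius` (px).
#' @param fps Video frame rate (frames/s).
#' @param radiusFactor Distance gate as a multiple of the cup radius.
#' @param angleMaxDeg Facing gate (degrees).
#' @param vertex `"nose"` or `"body"`.
#' @return List with `interaction_s` (named seconds per cup),
#'   `social_index`, and `skipped_frames`.
#' @export
socialInteraction <- function(frames, cups, fps, radiusFactor = 1.3,
                              angleMaxDeg = 90, vertex = c("nose", "body")) {
  vertex <- match.arg(vertex)
  if (fps <= 0) stopf("fps must be > 0")
  if (!all(c("social", "nonsocial") %in% cups$cup))
    stopf("cups must describe a 'social' and a 'nonsocial' cup")
  if (any(cups$radius <= 0)) stopf("cup radius must be > 0")
  nose <- cbind(frames$nose_x, frames$nose_y)
  body <- cbind(frames$body_x, frames$body_y)
  ok <- stats::complete.cases(nose, body)
  secondsAt <- function(cupName) {
    cup <- cups[cups$cup == cupName, ][1, ]
    center <- c(cup$x, cup$y)
    d <- sqrt((nose[, 1] - center[1])^2 + (nose[, 2] - center[2])^2)
    u <- nose - body                                   # body -> nose
    v <- if (vertex == "nose")
      cbind(center[1] - nose[, 1], center[2] - nose[, 2])  # nose -> cup
    else
      cbind(center[1] - body[, 1], center[2] - body[, 2])  # body -> cup
    cosang <- rowSums(u * v) / (rowNorms(u) * rowNorms(v))
    ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
    hit <- ok & d <= radiusFactor * cup$radius & ang <= angleMaxDeg
    sum(hit, na.rm = TRUE) / fps
  }
  sec <- c(social = secondsAt("social"), nonsocial = secondsAt("nonsocial"))
  if (sum(sec) == 0)
    stopf("social index undefined: no interaction frames at either cup")
  list(interaction_s = sec,
       social_index = unname(sec["social"] / sum(sec)),
       skipped_frames = sum(!ok))
}
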