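## Behavioral phenotyping: sucrose preference and k-means classification of
## stressed mice into resilient / susceptible (/ neutral) groups, with
## within-cluster sum-of-squares (WCSS) elbow model selection.

#' Sucrose preference score
#'
#' Preference = sucrose licks / (sucrose + water licks) x 100, the standard
#' anhedonia readout of the sucrose preference test.
#'
#' @param sucroseLicks,waterLicks Non-negative lick counts.
#' @return Preference in percent, in \[0, 100\].
#' @examples
#' sucrosePreference(75, 25)  # 75
#' @export
sucrosePreference <- function(sucroseLicks, waterLicks) {
  if (any(sucroseLicks < 0) || any(waterLicks < 0))
    stopf("lick counts must be non-negative")
  tot <- sucroseLicks + waterLicks
  if (any(tot == 0))
    stopf("undefined preference: no licks on either spout")
  100 * sucroseLicks / tot
}

## One seeded k-means solve with >= `restarts` random starts plus a
## warm start that splits the worst-fit point off the previous solution;
## the warm start guarantees WCSS(k) <= WCSS(k - 1) when `prev` is given.
bestKmeans <- function(x, k, restarts, prev = NULL) {
  x <- as.matrix(x)
  ux <- unique(x)
  if (k == nrow(ux)) {
    ## one cluster per distinct point: exact zero-dispersion solution
    cl <- match(apply(x, 1, paste, collapse = "\r"),
                apply(ux, 1, paste, collapse = "\r"))
    return(list(cluster = cl, centers = ux, tot.withinss = 0))
  }
  fit <- NULL
  for (attempt in 1:20) {
    fit <- tryCatch(stats::kmeans(x, centers = k, nstart = restarts,
                                  iter.max = 100),
                    error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) stopf("k-means failed for k = %d", k)
  if (!is.null(prev)) {
    d <- rowSums((x - prev$centers[prev$cluster, , drop = FALSE])^2)
    split <- x[which.max(d), , drop = FALSE]
    centers <- rbind(prev$centers, split)
    if (!anyDuplicated(centers)) {
      warm <- tryCatch(stats::kmeans(x, centers = centers, iter.max = 100),
                       error = function(e) NULL)
      if (!is.null(warm) && warm$tot.withinss < fit$tot.withinss) fit <- warm
    }
  }
  fit
}

#' Within-cluster sum-of-squares curve
#'
#' WCSS of the best k-means solution for k = 1 .. `kMax`, used for elbow
#' model selection. Each k uses at least `restarts` random starts plus a
#' warm start derived from the k - 1 solution, which makes the returned
#' curve non-increasing in k. `scores` may be a numeric vector (the usual
#' 1-D sucrose-preference clustering) or a matrix with one row per mouse
#' (e.g. the joint social-index x preference variant).
#'
#' @param scores Numeric vector or matrix of scores.
#' @param kMax Largest k to evaluate; must not exceed the number of distinct
#'   score rows.
#' @param restarts Random restarts per k (default 50).
#' @param seed Integer seed.
#' @return Numeric vector `wcss[k]`, k = 1 .. `kMax`.
#' @export
wcssCurve <- function(scores, kMax, restarts = 50L, seed = 1L) {
  x <- as.matrix(scores)
  nDistinct <- nrow(unique(x))
  if (kMax > nDistinct)
    stopf("kMax (%d) exceeds the number of distinct scores (%d)",
          kMax, nDistinct)
  withr::with_seed(as.integer(seed), {
    wcss <- numeric(kMax)
    prev <- NULL
    for (k in seq_len(kMax)) {
      fit <- bestKmeans(x, k, restarts, prev)
      wcss[k] <- fit$tot.withinss
      prev <- fit
    }
    wcss
  })
}

#' Elbow selection on a WCSS curve
#'
#' Picks the k at the bend of the WCSS curve. The default `"chord"` rule is
#' the knee heuristic applied on a variance-stabilized scale: WCSS values
#' are cube-root transformed (the Wilson-Hilferty transform, appropriate
#' for sum-of-squares quantities), both axes are rescaled to \[0, 1\], and
#' the interior k lying furthest below the straight line joining the first
#' and last curve points is selected. The `"curvature"` alternative
#' maximizes the raw discrete second difference
#' `wcss[k-1] - 2 wcss[k] + wcss[k+1]`; it is scale-dominated by the first
#' drop of the curve and tends to collapse to k = 2 on multi-cluster data,
#' which is why `"chord"` is the default. Under either rule ties break
#' toward the smallest k (a perfectly linear WCSS decline yields the first
#' interior k). Deterministic.
#'
#' @param wcss Per-k WCSS values (k = 1 .. length(wcss)), at least 3.
#' @param method `"chord"` (default) or `"curvature"`.
#' @return Selected k (integer).
#' @examples
#' selectKElbow(c(100, 10, 9, 8.5))  # 2
#' @export
selectKElbow <- function(wcss, method = c("chord", "curvature")) {
  method <- match.arg(method)
  nk <- length(wcss)
  if (nk < 3L) stopf("elbow selection needs at least 3 k values")
  ks <- 2:(nk - 1L)
  score <- if (method == "curvature") {
    wcss[ks - 1L] - 2 * wcss[ks] + wcss[ks + 1L]
  } else {
    tw <- pmax(wcss, 0)^(1 / 3)              # variance-stabilized WCSS
    span <- max(tw[1] - tw[nk], SD_FLOOR)
    y <- (tw - tw[nk]) / span                # 1 at k = 1, 0 at k = kMax
    chord <- 1 - (ks - 1) / (nk - 1)         # straight decline on [0, 1]^2
    chord - y[ks]                            # drop below the chord
  }
  as.integer(ks[which.max(score)])   # which.max takes the first maximum
}

#' Assign anhedonia phenotypes by k-means on sucrose preference
#'
#' Clusters the post-stress sucrose-preference scores of stressed mice with
#' seeded k-means (at least 50 restarts, best-WCSS solution kept) and maps
#' clusters to phenotypes by their mean preference: lowest mean =
#' susceptible, highest = resilient, and for k = 3 the middle cluster =
#' neutral (for k > 3 every interior cluster is labeled neutral). Control
#' mice are never entered into the clustering; they are labeled `control`
#' directly.
#'
#' @param stressedScores Named numeric vector, mouse id -> preference (%).
#' @param controlIds Character vector of control mouse ids.
#' @param k Number of clusters (>= 2, <= number of stressed mice).
#' @param seed Integer seed.
#' @param restarts Random restarts (>= 50 enforced).
#' @return A [PhenotypeAssignment-class] object.
#' @rdname assignPhenotypes
#' @export
assignPhenotypes <- function(stressedScores, controlIds = character(),
                             k = 3L, seed = 1L, restarts = 50L) {
  restarts <- max(50L, as.integer(restarts))
  ctrl <- data.frame(mouse_id = as.character(controlIds),
                     label = rep("control", length(controlIds)),
                     cluster = rep(NA_integer_, length(controlIds)),
                     stringsAsFactors = FALSE)
  if (length(stressedScores) == 0L) {
    return(new("PhenotypeAssignment", table = ctrl,
               clusterMeans = numeric(), kSelected = 0L, wcss = numeric()))
  }
  if (k < 2L) stopf("k must be >= 2")
  if (k > length(stressedScores))
    stopf("k (%d) exceeds the number of stressed mice (%d)",
          k, length(stressedScores))
  if (is.null(names(stressedScores)))
    names(stressedScores) <- paste0("mouse_", seq_along(stressedScores))
  fit <- withr::with_seed(as.integer(seed),
                          bestKmeans(stressedScores, k, restarts))
  means <- as.numeric(fit$centers)
  ord <- order(means)                 # rank clusters by mean preference
  rank <- match(seq_len(k), ord)      # cluster id -> rank (1 = lowest mean)
  lab <- rep("neutral", k)
  lab[rank == 1L] <- "susceptible"
  lab[rank == k] <- "resilient"
  stressed <- data.frame(mouse_id = names(stressedScores),
                         label = lab[fit$cluster],
                         cluster = rank[fit$cluster],
                         stringsAsFactors = FALSE)
  new("PhenotypeAssignment",
      table = rbind(ctrl, stressed),
      clusterMeans = sort(means), kSelected = as.integer(k),
      wcss = numeric())
}

#' Phenotype a cohort's behavioral score table
#'
#' Convenience wrapper: extracts the post-stress sucrose-preference scores of
#' stressed mice from a behavioral score table (as produced by
#' [cohortBehavior()] or read from file), computes the WCSS curve, selects k
#' via the elbow rule when `k = "auto"`, and assigns phenotypes.
#'
#' @param behavior Data frame with mouse_id, epoch and either spt_percent or
#'   sucrose_licks/water_licks columns.
#' @param mice Data frame with mouse_id and group_raw (`"stressed"` /
#'   `"control"`).
#' @param epoch Epoch whose scores are clustered (default the post-stress
#'   time point).
#' @param k Integer, or `"auto"` for elbow selection over k = 1 .. `kMax`.
#' @param kMax Largest k scanned when `k = "auto"`.
#' @inheritParams assignPhenotypes
#' @return A [PhenotypeAssignment-class] object with the WCSS curve filled in.
#' @export
phenotypeFromBehavior <- function(behavior, mice, epoch = postStressEpoch(),
                                  k = "auto", kMax = 8L, seed = 1L,
                                  restarts = 50L) {
  b <- behavior[behavior$epoch == epoch, , drop = FALSE]
  if (!nrow(b)) stopf("no behavioral scores for epoch '%s'", epoch)
  if (is.null(b$spt_percent))
    b$spt_percent <- sucrosePreference(b$sucrose_licks, b$water_licks)
  stressedIds <- mice$mouse_id[mice$group_raw == "stressed"]
  controlIds <- mice$mouse_id[mice$group_raw == "control"]
  scores <- stats::setNames(b$spt_percent, b$mouse_id)[stressedIds]
  kMax <- min(kMax, length(unique(scores)))
  wcss <- wcssCurve(scores, kMax = kMax, restarts = restarts, seed = seed)
  kSel <- if (identical(k, "auto")) selectKElbow(wcss) else as.integer(k)
  out <- assignPhenotypes(scores, controlIds, k = kSel, seed = seed,
                          restarts = restarts)
  out@wcss <- wcss
  out
}
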