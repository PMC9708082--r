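#' Stimulus preference of a unit
#'
#' Preference is determined by higher spike counts: 'A' if the mean A-alone
#' count exceeds the mean B-alone count, 'B' if lower. An exact tie (only
#' possible before screening, which guarantees separated rates) is flagged
#' and the unit excluded from preference-based analyses.
#'
#' @param countsA,countsB single-stimulus spike counts.
#' @return list with \code{preferred} ("A", "B" or NA) and \code{tie}.
#' @export
preference <- function(countsA, countsB) {
  mA <- mean(.checkCounts(countsA, "countsA"))
  mB <- mean(.checkCounts(countsB, "countsB"))
  if (mA == mB) return(list(preferred = NA_character_, tie = TRUE))
  list(preferred = if (mA > mB) "A" else "B", tie = FALSE)
}

#' Spike-count (noise) correlation between two units
#'
#' Pearson correlation of the two units' spike counts across paired
#' presentations of one stimulus condition. Presentations where either
#' unit's count deviates more than \code{outlierSD} standard deviations from
#' its own condition mean (mean and SD computed once, on all presentations
#' including the candidate) are excluded first.
#'
#' @param x,y paired spike counts of the two units.
#' @param outlierSD outlier threshold in SDs (default 3).
#' @param minN minimum presentations after exclusion (default 3).
#' @return list with \code{r}, \code{nUsed} and \code{flag} ("" if ok;
#'   \code{r} is NA with an explanatory flag otherwise).
#' @examples
#' spikeCountCorrelation(c(2, 0, 4, 2), c(1, 3, 1, 3))  # r = -0.707
#' @export
spikeCountCorrelation <- function(x, y, outlierSD = 3, minN = 3) {
  if (length(x) != length(y)) stop("x and y must be paired")
  ok <- function(v) {
    s <- stats::sd(v)
    if (is.na(s) || s == 0) rep(TRUE, length(v))
    else abs(v - mean(v)) <= outlierSD * s
  }
  keep <- ok(x) & ok(y)
  xs <- x[keep]; ys <- y[keep]
  if (length(xs) < minN)
    return(list(r = NA_real_, nUsed = length(xs), flag = "too_few"))
  if (stats::sd(xs) == 0 || stats::sd(ys) == 0)
    return(list(r = NA_real_, nUsed = length(xs), flag = "zero_variance"))
  list(r = stats::cor(xs, ys), nUsed = length(xs), flag = "")
}

#' Assignment-score correlation between two 'mixture' units
#'
#' Pearson correlation of the per-presentation assignment scores of two units
#' across their shared dual-stimulus presentations. Meaningful when both
#' units' dual-stimulus responses are classified as mixtures: a positive
#' value means the two units tended to signal the same stimulus on the same
#' presentation.
#'
#' @param scoresI,scoresJ aligned assignment scores of the two units.
#' @param minN minimum shared presentations (default 3).
#' @return list with \code{r}, \code{nUsed}, \code{flag}.
#' @export
assignmentCorrelation <- function(scoresI, scoresJ, minN = 3) {
  if (length(scoresI) != length(scoresJ)) stop("scores must be aligned")
  if (length(scoresI) < minN)
    return(list(r = NA_real_, nUsed = length(scoresI), flag = "too_few"))
  if (stats::sd(scoresI) == 0 || stats::sd(scoresJ) == 0)
    return(list(r = NA_real_, nUsed = length(scoresI),
                flag = "zero_variance"))
  list(r = stats::cor(scoresI, scoresJ), nUsed = length(scoresI), flag = "")
}

#' Congruence and model-class labels for a unit pair
#'
#' A pair has congruent preference when both units respond more strongly to
#' the same single stimulus, incongruent otherwise. The model-class
#' combination is the unordered pair of winning hypotheses.
#'
#' @param prefI,prefJ preference labels ("A" or "B") for the same condition
#'   key.
#' @param classI,classJ winning model categories.
#' @param conditionKeyI,conditionKeyJ optional condition keys; must match
#'   when given.
#' @return list with \code{congruence} and \code{classCombo} (e.g.
#'   "mixture|single", alphabetical).
#' @export
labelPair <- function(prefI, prefJ, classI, classJ,
                      conditionKeyI = NULL, conditionKeyJ = NULL) {
  if (!is.null(conditionKeyI) && !is.null(conditionKeyJ) &&
      conditionKeyI != conditionKeyJ)
    stop("pair members come from different condition keys")
  stopifnot(prefI %in% c("A", "B"), prefJ %in% c("A", "B"))
  list(congruence = if (prefI == prefJ) "congruent" else "incongruent",
       classCombo = paste(sort(c(classI, classJ)), collapse = "|"))
}

#' Shuffle test for a difference of medians
#'
#' Two-sided permutation test of the difference between group medians:
#' group labels are shuffled \code{nShuffles} times and the absolute median
#' difference recomputed; the add-one-corrected p-value is
#' \code{(1 + #(shuffled >= observed)) / (nShuffles + 1)}. An observed
#' difference exceeding every shuffle is reported as p < 1/nShuffles.
#'
#' @param group1,group2 numeric vectors (e.g. spike-count correlations of
#'   congruent and incongruent pairs).
#' @param nShuffles number of label shuffles (default 10000).
#' @param seed optional RNG seed.
#' @return list with \code{p}, \code{observed} (signed median difference
#'   group1 - group2), \code{nShuffles}, \code{seed}.
#' @export
medianShuffleTest <- function(group1, group2, nShuffles = 10000,
                              seed = NULL) {
  if (!length(group1) || !length(group2))
    stop("both groups must be non-empty")
  g1 <- group1[!is.na(group1)]; g2 <- group2[!is.na(group2)]
  if (!length(g1) || !length(g2))
    stop("both groups must contain non-missing values")
  obs <- stats::median(g1) - stats::median(g2)
  pool <- c(g1, g2); n1 <- length(g1); n <- length(pool)
  ge <- withSeed(seed, {
    count <- 0L
    for (s in seq_len(nShuffles)) {
      idx <- sample.int(n, n1)
      d <- stats::median(pool[idx]) - stats::median(pool[-idx])
      if (abs(d) >= abs(obs)) count <- count + 1L
    }
    count
  })
  list(p = (1 + ge) / (nShuffles + 1), observed = obs,
       nShuffles = nShuffles,
       seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

#' Build pair records for a classified population
#'
#' For every unordered pair of units sharing a session and condition key,
#' one record per stimulus set: the dual-stimulus (AB) presentations and the
#' A-alone and B-alone presentations each contribute a separate observation
#' (records are never averaged across conditions). Each record carries the
#' spike-count correlation, the assignment-score correlation (mixture-mixture
#' pairs on AB presentations only), the preference-congruence label and the
#' unordered model-class combination. For single-stimulus records the
#' \code{driven} column says whether the presented stimulus was the one
#' eliciting the stronger response from both units (both driven), neither, or
#' mixed.
#'
#' @param tripletList list of screened \linkS4class{Triplet} objects (one per
#'   unit for a shared condition key/session).
#' @param classifications list of \linkS4class{ModelPosterior} objects
#'   aligned with \code{tripletList}.
#' @param outlierSD outlier threshold passed to
#'   \code{\link{spikeCountCorrelation}}.
#' @param minN minimum usable presentations per record (default 3).
#' @return data.frame of pair records.
#' @export
pairRecords <- function(tripletList, classifications, outlierSD = 3,
                        minN = 3) {
  stopifnot(length(tripletList) == length(classifications))
  n <- length(tripletList)
  prefs <- lapply(tripletList, function(t)
    preference(countsA(t), countsB(t)))
  rows <- list(); k <- 0L
  for (i in seq_len(n - 1)) {
    ti <- tripletList[[i]]
    for (j in seq((i + 1), n)) {
      tj <- tripletList[[j]]
      if (conditionKey(ti) != conditionKey(tj)) next
      if (unitId(ti) == unitId(tj)) next
      if (prefs[[i]]$tie || prefs[[j]]$tie) next
      lab <- labelPair(prefs[[i]]$preferred, prefs[[j]]$preferred,
                       winner(classifications[[i]]),
                       winner(classifications[[j]]))
      for (ss in c("AB", "A_alone", "B_alone")) {
        xi <- switch(ss, AB = countsAB(ti), A_alone = countsA(ti),
                     B_alone = countsB(ti))
        xj <- switch(ss, AB = countsAB(tj), A_alone = countsA(tj),
                     B_alone = countsB(tj))
        if (length(xi) != length(xj)) next
        sc <- spikeCountCorrelation(xi, xj, outlierSD = outlierSD,
                                    minN = minN)
        ras <- NA_real_
        if (ss == "AB" &&
            winner(classifications[[i]]) == "mixture" &&
            winner(classifications[[j]]) == "mixture") {
          ac <- assignmentCorrelation(assignmentScores(classifications[[i]]),
                                      assignmentScores(classifications[[j]]),
                                      minN = minN)
          ras <- ac$r
        }
        driven <- NA_character_
        if (ss != "AB") {
          stim <- if (ss == "A_alone") "A" else "B"
          di <- prefs[[i]]$preferred == stim
          dj <- prefs[[j]]$preferred == stim
          driven <- if (di && dj) "both" else if (!di && !dj) "neither"
                    else "mixed"
        }
        k <- k + 1L
        rows[[k]] <- data.frame(
          unit_i = unitId(ti), unit_j = unitId(tj),
          condition_key = conditionKey(ti), stimulus_set = ss,
          r_sc = sc$r, r_as = ras, n_used = sc$nUsed,
          congruence = lab$congruence, class_combo = lab$classCombo,
          driven = driven, flag = sc$flag)
      }
    }
  }
  if (!k) return(data.frame())
  do.call(rbind, rows)
}

#' Population medians by congruence and model class
#'
#' Median spike-count correlation (and assignment-score correlation where
#' defined) per cell of congruence x model-class combination x stimulus set,
#' with per-cell n and a shuffle-test p-value for each
#' congruent-vs-incongruent contrast. Dual-stimulus records are reported per
#' class combination (including the 3x3 grid over mixture, intermediate and
#' single); single-stimulus records are pooled across A-alone and B-alone as
#' a baseline, optionally split by whether the presented stimulus drove both
#' units.
#'
#' @param records pair-record data.frame from \code{\link{pairRecords}}.
#' @param nShuffles shuffles per contrast (default 10000).
#' @param seed optional RNG seed.
#' @param splitDriven also split single-stimulus baseline cells by the
#'   \code{driven} label (default FALSE).
#' @return list with \code{medians} (data.frame, one row per cell) and
#'   \code{shuffleTests} (data.frame, one row per contrast).
#' @export
summarizePopulation <- function(records, nShuffles = 10000, seed = NULL,
                                splitDriven = FALSE) {
  if (!nrow(records)) stop("no pair records")
  records$cell_set <- ifelse(records$stimulus_set == "AB", "AB",
                             "single_stimulus")
  records$cell_combo <- ifelse(records$cell_set == "AB",
                               records$class_combo, "all")
  if (splitDriven && any(records$cell_set == "single_stimulus"))
    records$cell_combo[records$cell_set == "single_stimulus"] <-
      records$driven[records$cell_set == "single_stimulus"]
  cells <- split(records, list(records$cell_set, records$cell_combo,
                               records$congruence), drop = TRUE)
  med <- do.call(rbind, lapply(cells, function(d) data.frame(
    stimulus_set = d$cell_set[1], class_combo = d$cell_combo[1],
    congruence = d$congruence[1],
    median_r_sc = stats::median(d$r_sc, na.rm = TRUE),
    median_r_as = if (all(is.na(d$r_as))) NA_real_
                  else stats::median(d$r_as, na.rm = TRUE),
    n = sum(!is.na(d$r_sc)))))
  rownames(med) <- NULL
  groups <- split(records, list(records$cell_set, records$cell_combo),
                  drop = TRUE)
  sh <- list(); k <- 0L
  for (g in groups) {
    g1 <- g$r_sc[g$congruence == "congruent" & !is.na(g$r_sc)]
    g2 <- g$r_sc[g$congruence == "incongruent" & !is.na(g$r_sc)]
    k <- k + 1L
    if (!length(g1) || !length(g2)) {
      sh[[k]] <- data.frame(stimulus_set = g$cell_set[1],
                            class_combo = g$cell_combo[1],
                            p = NA_real_, observed = NA_real_,
                            n_congruent = length(g1),
                            n_incongruent = length(g2))
    } else {
      st <- medianShuffleTest(g1, g2, nShuffles = nShuffles,
                              seed = childSeed(seed, k))
      sh[[k]] <- data.frame(stimulus_set = g$cell_set[1],
                            class_combo = g$cell_combo[1],
                            p = st$p, observed = st$observed,
                            n_congruent = length(g1),
                            n_incongruent = length(g2))
    }
  }
  list(medians = med, shuffleTests = do.call(rbind, sh))
}
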