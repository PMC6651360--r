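#' Construct a scenario specification
#'
#' @param stage Experiment stage (0, 1 or 2).
#' @param name Scenario name.
#' @param coverRange Inclusive cover range in percent for target training
#'   polygons.
#' @param nTargetTrain Number of target training polygons.
#' @param nBackgroundTrain Number of background training polygons.
#' @param seed Integer seed for polygon selection.
#' @return A \linkS4class{ScenarioSpec}.
#' @export
scenarioSpec <- function(stage, name, coverRange, nTargetTrain = 30L,
                         nBackgroundTrain = 100L, seed = 1L) {
  new("ScenarioSpec", stage = as.integer(stage), name = name,
      coverRange = as.numeric(coverRange),
      nTargetTrain = as.integer(nTargetTrain),
      nBackgroundTrain = as.integer(nBackgroundTrain),
      seed = as.integer(seed))
}

# The Stage-1 cover-range grid.
stage1Ranges <- function() {
  list(SC0 = c(20, 70), SC1 = c(20, 100), SC2 = c(50, 100),
       SC3 = c(70, 100), SC4 = c(80, 100))
}

# Strata whose decile cover values intersect an inclusive range.
strataInRange <- function(coverRange) {
  strataLevels[vapply(strataLevels, function(s) {
    any(stratumDeciles(s) >= coverRange[1] & stratumDeciles(s) <= coverRange[2])
  }, logical(1))]
}

# Equal allocation over strata with remainder to the highest stratum,
# then redistribution of per-stratum shortfalls (preferring higher
# strata) when a stratum's eligible pool is too small.
allocateEqual <- function(n, strata, eligible) {
  k <- length(strata)
  alloc <- stats::setNames(rep(n %/% k, k), strata)
  alloc[k] <- alloc[k] + n - sum(alloc)
  redistribute(alloc, eligible, n)
}

# Allocation proportional to a reference allocation (largest-remainder
# rounding, ties and remainders to the highest stratum), then shortfall
# redistribution.
allocateProportional <- function(n, refAlloc, eligible) {
  q <- refAlloc * n / sum(refAlloc)
  alloc <- floor(q)
  rem <- n - sum(alloc)
  if (rem > 0) {
    frac <- q - alloc
    ord <- order(-frac, -seq_along(frac))  # ties to the highest stratum
    alloc[ord[seq_len(rem)]] <- alloc[ord[seq_len(rem)]] + 1
  }
  redistribute(alloc, eligible, n)
}

redistribute <- function(alloc, eligible, n) {
  if (sum(eligible) < n)
    stop("training pool too small: need ", n, " polygons, only ",
         sum(eligible), " eligible")
  alloc <- pmin(alloc, eligible)
  while (sum(alloc) < n) {
    spare <- eligible - alloc
    i <- max(which(spare > 0))  # prefer the highest stratum
    add <- min(n - sum(alloc), spare[i])
    alloc[i] <- alloc[i] + add
  }
  as.integer(alloc) |> stats::setNames(names(alloc))
}

# Seeded per-stratum permutation of eligible polygon ids; fixed per
# (seed, stratum) so Stage-2 subsets nest and n = 30 reproduces Stage 1.
stratumPermutation <- function(ids, seed, stratum) {
  set.seed(as.integer(seed) + match(stratum, strataLevels))
  ids[sample.int(length(ids))]
}

trainingPool <- function(design, fixedValidation) {
  m <- polygonMeta(design)
  list(
    target = setdiff(m$id[m$klass == "target"], fixedValidation$target),
    background = setdiff(m$id[m$klass == "background"],
                         fixedValidation$background)
  )
}

stage1Selection <- function(design, fixedValidation, spec, nTarget) {
  m <- polygonMeta(design)
  pool <- trainingPool(design, fixedValidation)
  strata <- strataInRange(spec@coverRange)
  eligible <- lapply(stats::setNames(strata, strata), function(s) {
    ids <- pool$target[m$stratum[match(pool$target, m$id)] == s]
    cp <- m$coverPct[match(ids, m$id)]
    sort(ids[cp >= spec@coverRange[1] & cp <= spec@coverRange[2]])
  })
  counts <- vapply(eligible, length, integer(1))
  allocRef <- allocateEqual(spec@nTargetTrain, strata, counts)
  alloc <- if (nTarget == spec@nTargetTrain) allocRef
           else allocateProportional(nTarget, allocRef, counts)
  target <- unlist(lapply(strata, function(s) {
    stratumPermutation(eligible[[s]], spec@seed, s)[seq_len(alloc[[s]])]
  }), use.names = FALSE)
  list(target = target, background = sort(pool$background),
       allocation = alloc)
}

#' Build a Stage-1 training set
#'
#' Selects \code{spec@nTargetTrain} target polygons (default 30) whose
#' cover percentage lies in the scenario's cover range, allocated equally
#' across the strata intersecting the range (remainder to the highest
#' stratum; shortfalls in a stratum whose pool is too small are
#' redistributed to the remaining strata, highest first), plus the
#' constant 100-polygon background training set shared by every scenario.
#'
#' @param design A \linkS4class{SampleDesign}.
#' @param fixedValidation Fixed validation set from
#'   \code{\link{buildFixedValidation}}.
#' @param spec A Stage-1 \linkS4class{ScenarioSpec}.
#' @return List with \code{target} and \code{background} id vectors and
#'   the per-stratum \code{allocation}.
#' @export
buildStage1Training <- function(design, fixedValidation, spec) {
  stopifnot(is(spec, "ScenarioSpec"))
  if (spec@stage != 1L) stop("spec must be a Stage-1 scenario")
  stage1Selection(design, fixedValidation, spec, spec@nTargetTrain)
}

#' Build a Stage-2 training set (varying training-set size)
#'
#' Keeps the cover range of the best Stage-1 scenario and scales the
#' per-stratum allocation proportionally to \code{nTarget} (largest-
#' remainder rounding, remainder to the highest stratum). Selection is
#' seeded and nested: the 20-polygon set is a subset of the 30-polygon
#' set, which is a subset of the 40-polygon set, so comparisons isolate
#' the effect of sample size. With \code{nTarget = 30} the polygon set is
#' identical to the best Stage-1 scenario's. The background training set
#' and the validation set are unchanged.
#'
#' @param design A \linkS4class{SampleDesign}.
#' @param fixedValidation Fixed validation set.
#' @param bestStage1Spec The winning Stage-1 \linkS4class{ScenarioSpec}.
#' @param nTarget Number of target training polygons (20, 30 or 40).
#' @return List with \code{target}, \code{background}, \code{allocation}.
#' @export
buildStage2Training <- function(design, fixedValidation, bestStage1Spec,
                                nTarget) {
  stopifnot(is(bestStage1Spec, "ScenarioSpec"))
  if (!nTarget %in% c(20L, 30L, 40L))
    stop("nTarget must be 20, 30 or 40")
  stage1Selection(design, fixedValidation, bestStage1Spec,
                  as.integer(nTarget))
}

#' Enumerate the full three-stage experiment
#'
#' Stage 0 (one random-split run), Stage 1 (the five cover-range
#' scenarios SC0-SC4) and Stage 2 (training-set sizes 20/30/40 for the
#' best Stage-1 scenario): nine classification runs in stage order.
#'
#' @param config An \linkS4class{ExperimentConfig}.
#' @param bestStage1Name Name of the best Stage-1 scenario (filled in by
#'   \code{\link{runExperiment}} after Stage-1 selection; defaults to
#'   "SC1" for a priori enumeration).
#' @return List of nine \linkS4class{ScenarioSpec} objects with unique
#'   names.
#' @export
enumerateExperiment <- function(config, bestStage1Name = "SC1") {
  seeds <- deriveSeeds(config@masterSeed,
                       c("stage0", paste0("sc", 0:4)))
  ranges <- stage1Ranges()
  if (!bestStage1Name %in% names(ranges))
    stop("unknown Stage-1 scenario: ", bestStage1Name)
  stage0 <- scenarioSpec(0L, "STAGE0", c(20, 100),
                         nTargetTrain = 55L, seed = seeds[["stage0"]])
  stage1 <- lapply(names(ranges), function(nm) {
    scenarioSpec(1L, nm, ranges[[nm]], nTargetTrain = 30L,
                 seed = seeds[[paste0("sc", substring(nm, 3))]])
  })
  bestSpec <- stage1[[match(bestStage1Name, names(ranges))]]
  stage2 <- lapply(c(20L, 30L, 40L), function(n) {
    scenarioSpec(2L, sprintf("%s_%d", bestStage1Name, n),
                 bestSpec@coverRange, nTargetTrain = n,
                 seed = bestSpec@seed)
  })
  c(list(stage0), stage1, stage2)
}
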