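#' Leave-one-subject-out and pooled split plans
#'
#' `losoFolds` builds one fold per subject: that subject's sessions are the
#' test set and the remaining subjects' sessions are shuffled and split 85/15
#' into training and validation at the session level. `pooledSplit` shuffles
#' all sessions and cuts 70/15/15 into train/validation/test. Both are
#' deterministic per seed and operate on session identifiers, so they accept
#' either a [SensorDataset-class] or a feature table with `session_id` and
#' `subject_id` columns.
#'
#' @param x a [SensorDataset-class] or a [sessionFeatures()] table.
#' @param valFraction fraction of the non-test sessions used for validation.
#' @param seed integer seed for the shuffles.
#' @return a `splitPlan`: list with `mode` and `folds`, each fold holding
#'   disjoint `train`, `val`, `test` session-id vectors (and the test
#'   `subject` for LOSO).
#' @export
losoFolds <- function(x, valFraction = 0.15, seed = 1) {
  tab <- .sessionTable(x)
  subjects <- unique(tab$subject_id)
  if (length(subjects) < 2)
    stopf("leave-one-subject-out needs at least 2 subjects")
  folds <- lapply(subjects, function(s) {
    test <- tab$session_id[tab$subject_id == s]
    rest <- tab$session_id[tab$subject_id != s]
    rest <- withSeed(subSeed(seed, paste0("loso_", s)), sample(rest))
    nVal <- max(1L, round(valFraction * length(rest)))
    list(subject = s, train = sort(rest[-seq_len(nVal)]),
         val = sort(rest[seq_len(nVal)]), test = sort(test))
  })
  structure(list(mode = "loso", folds = folds, seed = seed),
            class = "splitPlan")
}

#' @rdname losoFolds
#' @param trainFraction fraction of sessions for training in the pooled
#'   split (the remainder is halved between validation and test by
#'   `valFraction`).
#' @export
pooledSplit <- function(x, trainFraction = 0.70, valFraction = 0.15,
                        seed = 1) {
  tab <- .sessionTable(x)
  n <- nrow(tab)
  if (n < 7) stopf("pooled split needs at least 7 sessions")
  ids <- withSeed(subSeed(seed, "pooled"), sample(tab$session_id))
  nTrain <- round(trainFraction * n)
  nVal <- round(valFraction * n)
  fold <- list(train = sort(ids[seq_len(nTrain)]),
               val = sort(ids[nTrain + seq_len(nVal)]),
               test = sort(ids[(nTrain + nVal + 1):n]))
  structure(list(mode = "pooled", folds = list(fold), seed = seed),
            class = "splitPlan")
}

.sessionTable <- function(x) {
  if (is(x, "SensorDataset"))
    return(data.frame(session_id = sessionIds(x), subject_id = subjectIds(x),
                      stringsAsFactors = FALSE))
  if (is.data.frame(x) && all(c("session_id", "subject_id") %in% names(x)))
    return(unique(x[, c("session_id", "subject_id")]))
  stopf("need a SensorDataset or a feature table with session_id/subject_id")
}

#' Mean error and error SD of blood-pressure estimates
#'
#' `ME = mean(estimate - reference)`; `SD` is the sample standard deviation
#' (n - 1 denominator) of the differences.
#'
#' @param estimates,references mmHg vectors of equal length (>= 2).
#' @return an `errorStats` list: `me`, `sd`, `n`.
#' @export
errorStats <- function(estimates, references) {
  if (length(estimates) != length(references))
    stopf("estimates and references differ in length")
  if (length(estimates) < 2) stopf("need at least 2 paired readings")
  e <- estimates - references
  structure(list(me = mean(e), sd = sd(e), n = length(e)),
            class = "errorStats")
}

#' Bland-Altman limits of agreement
#'
#' `[mu - 1.96 sigma, mu + 1.96 sigma]` for difference mean `mu` and SD
#' `sigma`; exact arithmetic, rounding only at the reporting layer.
#'
#' @param me,sd mean and standard deviation of the differences, mmHg.
#' @return a `blandAltman` list: `mu`, `sigma`, `loaLower`, `loaUpper`.
#' @export
blandAltmanLimits <- function(me, sd) {
  if (sd < 0) stopf("sd must be non-negative")
  structure(list(mu = me, sigma = sd,
                 loaLower = me - 1.96 * sd, loaUpper = me + 1.96 * sd),
            class = "blandAltman")
}

#' AAMI accuracy criterion
#'
#' Pass iff `|ME| < 5` mmHg and `SD < 8` mmHg (strict inequalities; ties
#' fail).
#'
#' @param stats an [errorStats()] object.
#' @return logical.
#' @export
aamiCheck <- function(stats) {
  abs(stats$me) < 5 && stats$sd < 8
}

#' BHS cumulative-error grading
#'
#' Computes the percentages of absolute errors within 5, 10 and 15 mmHg and
#' grades them against the BHS protocol table: A requires 60/85/95, B
#' 50/75/90, C 40/65/85; anything less is D.
#'
#' @param errors mmHg vector of estimate minus reference differences.
#' @return list with `grade` and `pctLe5`, `pctLe10`, `pctLe15`.
#' @export
bhsGrade <- function(errors) {
  if (!length(errors)) stopf("need at least one error")
  a <- abs(errors)
  pct <- c(le5 = 100 * mean(a <= 5), le10 = 100 * mean(a <= 10),
           le15 = 100 * mean(a <= 15))
  grades <- list(A = c(60, 85, 95), B = c(50, 75, 90), C = c(40, 65, 85))
  grade <- "D"
  for (g in names(grades)) {
    if (all(pct >= grades[[g]])) { grade <- g; break }
  }
  list(grade = grade, pctLe5 = pct[["le5"]], pctLe10 = pct[["le10"]],
       pctLe15 = pct[["le15"]])
}

# Build X, y for one target from feature-table rows.
.designMatrix <- function(features, target) {
  nms <- featureNames(target)
  rows <- features[features$valid & !is.na(features$ref_sbp), , drop = FALSE]
  X <- as.matrix(rows[, nms, drop = FALSE])
  y <- if (target == "SBP") rows$ref_sbp else rows$ref_dbp
  list(X = X, y = y, rows = rows)
}

#' Run a split-plan experiment on a window-feature table
#'
#' For every fold: screens out zero-variance feature columns (they cannot be
#' standardized — e.g. `sex` when all training subjects share one), fits the
#' scaler and the MLP on the training sessions, early-stops on the
#' validation sessions, predicts the held-out test sessions, and pools the
#' test errors across folds into a single evaluation (a single
#' estimate/reference scatter rather than fold-averaged statistics).
#'
#' @param features a [datasetFeatures()] table.
#' @param target `"SBP"` or `"DBP"`.
#' @param cfg an [mlpConfig()]; its seed is combined with `seed`.
#' @param seed master seed for splitting and training.
#' @param plan optional pre-built `splitPlan`; defaults to LOSO folds.
#' @return a `bpEvaluation` report: pooled [errorStats()],
#'   [blandAltmanLimits()], AAMI flag, BHS grading, per-subject error
#'   summary, per-fold details, and the paired estimates/references.
#' @export
runExperiment <- function(features, target = c("SBP", "DBP"),
                          cfg = mlpConfig(), seed = 1, plan = NULL) {
  target <- match.arg(target)
  if (is.null(plan)) plan <- losoFolds(features, seed = seed)
  dm <- .designMatrix(features, target)
  if (length(unique(dm$rows$subject_id)) < 2 && plan$mode == "loso")
    stopf("LOSO experiment needs windows from at least 2 subjects")
  est <- numeric(); ref <- numeric(); subj <- character()
  foldInfo <- list()
  for (k in seq_along(plan$folds)) {
    fold <- plan$folds[[k]]
    iTr <- dm$rows$session_id %in% fold$train
    iVa <- dm$rows$session_id %in% fold$val
    iTe <- dm$rows$session_id %in% fold$test
    if (!any(iTr) || !any(iVa) || !any(iTe)) next
    Xtr <- dm$X[iTr, , drop = FALSE]
    keepCols <- apply(Xtr, 2, function(v) sd(v) > 1e-12)
    cfgFold <- cfg
    cfgFold$seed <- subSeed(seed, paste0("fold_", k, "_", cfg$seed))
    model <- trainModel(Xtr[, keepCols, drop = FALSE], dm$y[iTr],
                        dm$X[iVa, keepCols, drop = FALSE], dm$y[iVa],
                        cfgFold)
    p <- predictBP(model, dm$X[iTe, keepCols, drop = FALSE])
    est <- c(est, p)
    ref <- c(ref, dm$y[iTe])
    subj <- c(subj, dm$rows$subject_id[iTe])
    foldInfo[[k]] <- list(fold = k, testSubject = fold$subject %||% NA,
                          nTrain = sum(iTr), nTest = sum(iTe),
                          droppedColumns = colnames(dm$X)[!keepCols],
                          bestEpoch = model$bestEpoch,
                          valLoss = model$bestValLoss)
  }
  stats <- errorStats(est, ref)
  errs <- est - ref
  perSubject <- do.call(rbind, lapply(split(errs, subj), function(e)
    data.frame(n = length(e), me = mean(e),
               sd = if (length(e) > 1) sd(e) else NA_real_)))
  perSubject <- cbind(subject_id = rownames(perSubject), perSubject)
  rownames(perSubject) <- NULL
  structure(list(target = target, mode = plan$mode, stats = stats,
                 blandAltman = blandAltmanLimits(stats$me, stats$sd),
                 aamiPass = aamiCheck(stats), bhs = bhsGrade(errs),
                 perSubject = perSubject, folds = foldInfo,
                 estimates = est, references = ref, subjects = subj),
            class = "bpEvaluation")
}

#' @rdname runExperiment
#' @export
runLosoExperiment <- function(features, target = c("SBP", "DBP"),
                              cfg = mlpConfig(), seed = 1) {
  runExperiment(features, target, cfg, seed,
                plan = losoFolds(features, seed = seed))
}

#' @rdname runExperiment
#' @export
runPooledExperiment <- function(features, target = c("SBP", "DBP"),
                                cfg = mlpConfig(), seed = 1) {
  runExperiment(features, target, cfg, seed,
                plan = pooledSplit(features, seed = seed))
}

#' Error SD of the training-mean baseline predictor
#'
#' For each fold of a plan, predicts the training-set mean reference for
#' every test window; pools the errors. The fusion model must do
#' substantially better than this to demonstrate recoverable signal.
#'
#' @inheritParams runExperiment
#' @return an [errorStats()] object.
#' @export
meanPredictorStats <- function(features, target = c("SBP", "DBP"),
                               seed = 1, plan = NULL) {
  target <- match.arg(target)
  if (is.null(plan)) plan <- losoFolds(features, seed = seed)
  dm <- .designMatrix(features, target)
  est <- numeric(); ref <- numeric()
  for (fold in plan$folds) {
    iTr <- dm$rows$session_id %in% c(fold$train, fold$val)
    iTe <- dm$rows$session_id %in% fold$test
    if (!any(iTr) || !any(iTe)) next
    est <- c(est, rep(mean(dm$y[iTr]), sum(iTe)))
    ref <- c(ref, dm$y[iTe])
  }
  errorStats(est, ref)
}

#' @export
print.bpEvaluation <- function(x, ...) {
  cat(sprintf("Blood-pressure evaluation (%s, %s)\n", x$target, x$mode))
  cat(sprintf("  n windows : %d\n", x$stats$n))
  cat(sprintf("  ME +/- SD : %.2f +/- %.2f mmHg\n", x$stats$me, x$stats$sd))
  cat(sprintf("  LOA       : [%.2f, %.2f] mmHg\n",
              x$blandAltman$loaLower, x$blandAltman$loaUpper))
  cat(sprintf("  AAMI      : %s\n", if (x$aamiPass) "pass" else "fail"))
  cat(sprintf("  BHS       : grade %s (<=5/10/15 mmHg: %.1f/%.1f/%.1f%%)\n",
              x$bhs$grade, x$bhs$pctLe5, x$bhs$pctLe10, x$bhs$pctLe15))
  invisible(x)
}

#' Serialize an evaluation report to JSON
#'
#' @param report a `bpEvaluation`.
#' @param path output file.
#' @export
writeEvaluationReport <- function(report, path) {
  out <- list(target = report$target, mode = report$mode,
              n = report$stats$n, me = report$stats$me, sd = report$stats$sd,
              loa_lower = report$blandAltman$loaLower,
              loa_upper = report$blandAltman$loaUpper,
              aami_pass = report$aamiPass,
              bhs = report$bhs, per_subject = report$perSubject)
  writeLines(jsonlite::toJSON(out, auto_unbox = TRUE, digits = 10), path)
  invisible(path)
}
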