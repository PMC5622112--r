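#' Per-dose classification accuracy (dose-response curve)
#'
#' For every (duration, dose > 0) condition present in the table, runs the
#' four control-vs-treated classification trials — the 2 x 2 pairings of
#' the two experiments' control groups with the two experiments' treated
#' groups within a duration — each evaluated by stratified k-fold
#' cross-validation. Reports, per dose, the mean accuracy over the four
#' trials, the trial-to-trial standard error (n = 4) and the mean
#' cross-validation standard error (kept separate).
#'
#' @param table combined feature table (see [simulate_feature_study()]):
#'   must contain control rows (`dose_M == 0`) and treated rows per
#'   experiment and duration.
#' @param k folds for cross-validation.
#' @param C SVM regularization constant.
#' @param seed base seed (per-trial seeds derived deterministically).
#' @return object of class `dose_response_curve`: data.frame with columns
#'   `duration_h`, `dose_M`, `accuracy`, `se_trials`, `se_cv`, `n_trials`.
#' @export
dose_response_curve <- function(table, k = 10, C = 1, seed = 1) {
  fm <- feature_matrix(table)
  meta <- fm$meta
  rows <- list()
  for (dur in sort(unique(meta$duration_h))) {
    exps <- sort(unique(meta$experiment[meta$duration_h == dur]))
    ctrl <- lapply(exps, function(e)
      which(meta$duration_h == dur & meta$experiment == e & meta$dose_M == 0))
    names(ctrl) <- exps
    for (dose in sort(setdiff(unique(meta$dose_M[meta$duration_h == dur]), 0))) {
      trt <- lapply(exps, function(e)
        which(meta$duration_h == dur & meta$experiment == e &
                meta$dose_M == dose))
      names(trt) <- exps
      if (any(lengths(ctrl) == 0) || any(lengths(trt) == 0)) {
        warning("missing control or treated group at dose ", dose,
                " (", dur, " h); dose skipped")
        next
      }
      pair <- expand.grid(ce = exps, te = exps)
      accs <- ses <- numeric(nrow(pair))
      for (i in seq_len(nrow(pair))) {
        ic <- ctrl[[as.character(pair$ce[i])]]
        it <- trt[[as.character(pair$te[i])]]
        xi <- fm$x[c(ic, it), , drop = FALSE]
        yi <- rep(c("control", "treated"), c(length(ic), length(it)))
        cv <- cross_validate(xi, yi, k = k, C = C,
                             seed = (seed + 17 * i) %% 2147483647)
        accs[i] <- cv$accuracy; ses[i] <- cv$se
      }
      rows[[length(rows) + 1L]] <- data.frame(
        duration_h = dur, dose_M = dose, accuracy = mean(accs),
        se_trials = stats::sd(accs) / sqrt(length(accs)),
        se_cv = mean(ses), n_trials = nrow(pair))
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("dose_response_curve", class(out))
  out
}

#' Transfer matrix: one model applied across conditions
#'
#' Trains one linear SVM per (dose > 0, experiment) training condition —
#' on that experiment's control vs treated rows at that dose — and
#' evaluates it on every (dose, experiment) test condition's
#' control-vs-treated split. Every population is first split 50/50
#' (seeded) into a training and an evaluation half: models see only
#' training halves and all matrix cells are scored on evaluation halves,
#' so no cell — including the diagonal and same-experiment cells that
#' share a control population — ever scores data its model was trained
#' on. Missing conditions are `NA`, never 0.
#'
#' @param table combined feature table for one duration (rows with other
#'   durations are ignored if `duration` given).
#' @param duration duration (h) to analyze; default: the maximum present.
#' @param k unused (kept for interface stability).
#' @param C SVM regularization constant.
#' @param seed base seed (controls the half-splits and solver order).
#' @return object of class `transfer_matrix`: numeric matrix, rows =
#'   training conditions `"e<exp>@<dose>"`, columns = test conditions.
#' @export
transfer_matrix <- function(table, duration = NULL, k = 10, C = 1, seed = 1) {
  fm <- feature_matrix(table)
  meta <- fm$meta
  if (is.null(duration)) duration <- max(meta$duration_h)
  keep <- meta$duration_h == duration
  meta <- meta[keep, , drop = FALSE]
  x <- fm$x[keep, , drop = FALSE]
  exps <- sort(unique(meta$experiment))
  doses <- sort(setdiff(unique(meta$dose_M), 0))
  # seeded half-split of every (experiment, dose incl. control) population
  halves <- new.env(parent = emptyenv())
  half_of <- function(e, d) {
    key <- paste(e, d)
    if (is.null(halves[[key]])) {
      ii <- which(meta$experiment == e & meta$dose_M == d)
      tr <- .with_seed(seed + 31L * e + round(log10(d + 1e-12)),
                       sort(sample(ii, floor(length(ii) / 2))))
      halves[[key]] <- list(train = tr, eval = setdiff(ii, tr))
    }
    halves[[key]]
  }
  conds <- expand.grid(exp = exps, dose = doses)
  cname <- sprintf("e%d@%g", conds$exp, conds$dose)
  M <- matrix(NA_real_, nrow(conds), nrow(conds),
              dimnames = list(train = cname, test = cname))
  sets <- lapply(seq_len(nrow(conds)), function(i) {
    hc <- half_of(conds$exp[i], 0)
    ht <- half_of(conds$exp[i], conds$dose[i])
    if (length(hc$train) == 0 || length(ht$train) == 0) return(NULL)
    list(hc = hc, ht = ht)
  })
  for (i in seq_len(nrow(conds))) {
    si <- sets[[i]]
    if (is.null(si)) next
    tr <- c(si$hc$train, si$ht$train)
    ytr <- rep(c("control", "treated"),
               c(length(si$hc$train), length(si$ht$train)))
    m <- linear_svm(x[tr, , drop = FALSE], ytr, C = C,
                    seed = (seed + i) %% 2147483647,
                    meta = list(dose = conds$dose[i], exp = conds$exp[i],
                                duration = duration))
    for (j in seq_len(nrow(conds))) {
      sj <- sets[[j]]
      if (is.null(sj)) next
      te <- c(sj$hc$eval, sj$ht$eval)
      yte <- rep(c("control", "treated"),
                 c(length(sj$hc$eval), length(sj$ht$eval)))
      pr <- predict(m, x[te, , drop = FALSE])
      M[i, j] <- classification_accuracy(pr, yte)$A
    }
  }
  structure(M, class = c("transfer_matrix", "matrix"), duration = duration)
}

#' @export
print.transfer_matrix <- function(x, ...) {
  cat(sprintf("Transfer matrix (%g h): training condition x test condition\n",
              attr(x, "duration")))
  print(round(unclass(x), 3))
  invisible(x)
}
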