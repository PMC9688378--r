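#' Tracking-error GLMM
#'
#' The behavioral model: tracking error as response, CONDITION, GROUP and
#' their interaction as fixed effects, BLOCK as a covariate, participant
#' as random intercept; inverse-Gaussian family with identity link (the
#' combination selected by AIC among the standard candidates for
#' positively skewed, strictly positive errors). Optionally reduced by
#' backward stepwise elimination.
#'
#' @param behavior Per-trial behavior table (see [behavior_table()]).
#' @param family,link Response family and link.
#' @param stepwise Reduce the model by [stepwise_backward()]?
#' @return For `stepwise = TRUE` the stepwise result (spec, fit, trace);
#'   otherwise a `fit_result`.
#' @export
behavior_model <- function(behavior, family = "INVERSE_GAUSSIAN",
                           link = "IDENTITY", stepwise = TRUE) {
  dat <- behavior
  dat$condition <- factor(dat$condition)
  dat$group <- factor(dat$group)
  dat$block <- as.numeric(dat$block)
  spec <- model_spec("tracking_error",
                     c("condition", "group", "condition:group", "block"),
                     family = family, link = link)
  if (stepwise) stepwise_backward(spec, dat) else fit_model(spec, dat)
}

#' Stage-wise MRBD linear mixed model
#'
#' For one stage (planning or execution): MRBD (dB) as response;
#' CONDITION, GROUP, HEMISPHERE and REGION with all interactions up to
#' the 4-way initially included; participant as random intercept;
#' backward stepwise reduction.
#'
#' @param mrbd MRBD table from [extract_mrbd()].
#' @param stage `"planning"` or `"execution"`.
#' @param alpha Stepwise removal threshold.
#' @return Stepwise result (spec, fit, trace).
#' @export
stage_model <- function(mrbd, stage = c("planning", "execution"), alpha = 0.05) {
  stage <- match.arg(stage)
  dat <- mrbd[mrbd$stage == stage, ]
  for (f in c("condition", "group", "hemisphere", "region")) {
    dat[[f]] <- factor(dat[[f]])
  }
  base <- c("condition", "group", "hemisphere", "region")
  fixed <- unlist(lapply(seq_along(base), function(k) {
    utils::combn(base, k, paste, collapse = ":")
  }))
  spec <- model_spec("mrbd_db", fixed, family = "GAUSSIAN", link = "IDENTITY")
  stepwise_backward(spec, dat, alpha = alpha)
}

#' Wide MRBD predictor table
#'
#' One row per participant x condition with the 12 MRBD predictors
#' (stage x region x hemisphere), named like `planning_central_right`.
#'
#' @param mrbd MRBD table from [extract_mrbd()].
#' @return Wide data.frame.
#' @export
mrbd_wide <- function(mrbd) {
  mrbd$predictor <- paste(mrbd$stage, mrbd$region, mrbd$hemisphere, sep = "_")
  keys <- unique(mrbd[, c("participant", "group", "condition")])
  preds <- sort(unique(mrbd$predictor))
  for (p in preds) keys[[p]] <- NA_real_
  for (i in seq_len(nrow(keys))) {
    sel <- mrbd$participant == keys$participant[i] &
      mrbd$condition == keys$condition[i]
    sub <- mrbd[sel, ]
    for (p in preds) {
      keys[[p]][i] <- mean(sub$mrbd_db[sub$predictor == p])
    }
  }
  rownames(keys) <- NULL
  keys
}

#' MRBD-behavior association model
#'
#' Tracking error (mean per participant x condition) as response; the 12
#' regional MRBD predictors (left/right x frontal/central/parietal x
#' planning/execution), GROUP and CONDITION as fixed effects, plus the
#' interactions between each MRBD predictor and the factors named in
#' `interactions`; participant as random intercept; backward stepwise
#' reduction. Sign convention: a positive coefficient on an MRBD dB
#' predictor means less desynchronization goes with higher (worse)
#' tracking error.
#'
#' @param mrbd MRBD table from [extract_mrbd()].
#' @param behavior Per-trial behavior table.
#' @param interactions Factors to interact with the MRBD predictors:
#'   subset of `c("group", "condition")`.
#' @param alpha Stepwise removal threshold.
#' @return List: stepwise result plus the joined model `data`.
#' @export
association_model <- function(mrbd, behavior,
                              interactions = c("group", "condition"),
                              alpha = 0.05) {
  wide <- mrbd_wide(mrbd)
  beh <- stats::aggregate(tracking_error ~ participant + condition, behavior, mean)
  dat <- merge(wide, beh, by = c("participant", "condition"))
  if (nrow(dat) < nrow(wide)) {
    missing <- setdiff(paste(wide$participant, wide$condition),
                       paste(dat$participant, dat$condition))
    stop("behavior/MRBD join mismatch; unmatched keys: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  dat$group <- factor(dat$group)
  dat$condition <- factor(dat$condition)
  preds <- grep("^(planning|execution)_", names(dat), value = TRUE)
  fixed <- c(preds, "group", "condition")
  for (f in interactions) fixed <- c(fixed, paste(preds, f, sep = ":"))
  spec <- model_spec("tracking_error", fixed, family = "GAUSSIAN",
                     link = "IDENTITY")
  res <- stepwise_backward(spec, dat, alpha = alpha)
  res$data <- dat
  res
}

#' Per-group Spearman association between a predictor and tracking error
#'
#' Averages the predictor and the tracking error across conditions per
#' participant, then correlates within each group.
#'
#' @param mrbd MRBD table.
#' @param behavior Per-trial behavior table.
#' @param predictor Predictor name (default right-central planning MRBD).
#' @return data.frame with one row per group: `group`, `rho`, `p`, `n`.
#' @export
mrbd_behavior_correlation <- function(mrbd, behavior,
                                      predictor = "planning_central_right") {
  wide <- mrbd_wide(mrbd)
  beh <- stats::aggregate(tracking_error ~ participant + condition, behavior, mean)
  dat <- merge(wide, beh, by = c("participant", "condition"))
  per_part <- stats::aggregate(
    dat[, c(predictor, "tracking_error")],
    by = list(participant = dat$participant, group = dat$group), mean
  )
  out <- lapply(split(per_part, per_part$group), function(g) {
    sp <- spearman_assoc(g[[predictor]], g$tracking_error)
    data.frame(group = g$group[1L], rho = sp$rho, p = sp$p, n = nrow(g),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
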