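#' Benjamini-Hochberg step-up FDR procedure
#'
#' Adjusted p-values via the step-up monotone minimum (equivalent to
#' `p.adjust(method = "BH")`, which is used internally); the rejection
#' set is every hypothesis whose adjusted p-value is at most `q`, which
#' reproduces the step-up rule: reject the k smallest p-values where
#' `k = max{i : p_(i) <= i q / m}`.
#'
#' @param pvalues Numeric vector of p-values in [0, 1].
#' @param q FDR level in (0, 1).
#' @return List with `adjusted` (same order as input) and `reject`
#'   (logical).
#' @export
bh_fdr <- function(pvalues, q = 0.05) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  if (q <= 0 || q >= 1) stop("`q` must be in (0, 1)", call. = FALSE)
  adjusted <- stats::p.adjust(pvalues, method = "BH")
  list(adjusted = adjusted, reject = adjusted <= q)
}

#' Spearman rank correlation
#'
#' rho is the Pearson correlation of midranks (exact under ties). The
#' p-value uses the t-approximation for n > 8 and the exact permutation
#' distribution of rho for n <= 8.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return List with `rho`, `p`, `method`.
#' @export
spearman_assoc <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length", call. = FALSE)
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: constant input", call. = FALSE)
  }
  rx <- rank(x)
  ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= 8L) {
    perms <- permutations_of(n)
    rhos <- apply(perms, 1L, function(p) stats::cor(rx, ry[p]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    method <- "t approximation"
  }
  list(rho = rho, p = min(p, 1), method = method)
}

# All permutations of 1..n as a matrix (n <= 8).
permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (pos in seq_len(n)) {
    block <- cbind(sub[, seq_len(pos - 1L), drop = FALSE], n,
                   sub[, seq(pos, n - 1L)[seq_len(n - pos)], drop = FALSE])
    out[r + seq_len(nrow(sub)), ] <- block
    r <- r + nrow(sub)
  }
  out
}

#' Random draws from the inverse Gaussian distribution
#'
#' Michael-Schucany-Haas (1976) transformation method. Used by the
#' simulation oracles for the tracking-error GLMM.
#'
#' @param n Number of draws.
#' @param mean,shape Mean and shape (both > 0).
#' @return Numeric vector of positive draws.
#' @export
rinvgauss <- function(n, mean = 1, shape = 1) {
  stopifnot(all(mean > 0), all(shape > 0))
  y <- stats::rnorm(n)^2
  x <- mean + mean^2 * y / (2 * shape) -
    mean / (2 * shape) * sqrt(4 * mean * shape * y + mean^2 * y^2)
  u <- stats::runif(n)
  ifelse(u <= mean / (mean + x), x, mean^2 / x)
}

#' Mixed-model specification
#'
#' @param response Dependent-variable name.
#' @param fixed Character vector of fixed-effect terms (interactions as
#'   `"a:b"`); interaction terms require their marginal terms (hierarchy).
#' @param random Random-intercept grouping variable (default
#'   `"participant"`).
#' @param family `"GAUSSIAN"`, `"INVERSE_GAUSSIAN"` or `"GAMMA"`.
#' @param link `"IDENTITY"`, `"LOG"` or `"INVERSE"`.
#' @return A `model_spec` list.
#' @export
model_spec <- function(response, fixed, random = "participant",
                       family = c("GAUSSIAN", "INVERSE_GAUSSIAN", "GAMMA"),
                       link = c("IDENTITY", "LOG", "INVERSE")) {
  family <- match.arg(family)
  link <- match.arg(link)
  fixed <- unique(fixed)
  for (tm in fixed) {
    parts <- strsplit(tm, ":", fixed = TRUE)[[1L]]
    if (length(parts) > 1L) {
      for (k in seq_len(length(parts) - 1L)) {
        subs <- utils::combn(parts, k, paste, collapse = ":")
        missing <- subs[!vapply(subs, function(s) term_present(s, fixed), logical(1L))]
        if (length(missing)) {
          stop("interaction `", tm, "` requires marginal term(s): ",
               paste(missing, collapse = ", "), call. = FALSE)
        }
      }
    }
  }
  structure(list(response = response, fixed = fixed, random = random,
                 family = family, link = link),
            class = "model_spec")
}

# order-insensitive term matching ("a:b" == "b:a")
term_key <- function(tm) paste(sort(strsplit(tm, ":", fixed = TRUE)[[1L]]), collapse = ":")
term_present <- function(tm, terms) term_key(tm) %in% vapply(terms, term_key, character(1L))

spec_formula <- function(spec) {
  rhs <- if (length(spec$fixed)) paste(spec$fixed, collapse = " + ") else "1"
  stats::as.formula(paste0(spec$response, " ~ ", rhs, " + (1 | ", spec$random, ")"))
}

spec_family <- function(spec) {
  link <- c(IDENTITY = "identity", LOG = "log", INVERSE = "inverse")[[spec$link]]
  switch(spec$family,
    GAUSSIAN = stats::gaussian(link = link),
    INVERSE_GAUSSIAN = stats::inverse.gaussian(link = link),
    GAMMA = stats::Gamma(link = link)
  )
}

#' Fit a (generalized) linear mixed model
#'
#' Gaussian identity-link models are fitted with `lmerTest::lmer`
#' (maximum likelihood, Satterthwaite-based per-term F tests); other
#' family/link combinations with `lme4::glmer` (per-term Wald chi-square
#' via `car::Anova`). Non-convergence is flagged, never silent.
#'
#' @param spec A `model_spec`.
#' @param data data.frame containing all model variables.
#' @param nAGQ Number of adaptive Gauss-Hermite quadrature points for
#'   GLMM fits (1 = Laplace). Models here have a single scalar random
#'   intercept, so higher values are cheap and better calibrated when CI
#'   precision matters.
#' @return A `fit_result`: `fit`, `spec`, `aic`, `converged`,
#'   `coefficients` (estimates and standard errors), `term_tests`
#'   (per-term statistics and p-values), `test_method`, `warnings`.
#' @export
fit_model <- function(spec, data, nAGQ = 1L) {
  for (v in c(spec$response, spec$random)) {
    if (!v %in% names(data)) stop("variable `", v, "` not in data", call. = FALSE)
  }
  if (spec$family %in% c("INVERSE_GAUSSIAN", "GAMMA") &&
      any(data[[spec$response]] <= 0)) {
    stop("response must be strictly positive for family ", spec$family, call. = FALSE)
  }
  # fit inside an environment that carries the data, so downstream
  # consumers that re-evaluate the call (lmerTest, emmeans) can find it
  fit_env <- new.env(parent = getNamespace("betatrack"))
  fit_env$.fit_data <- data
  fml <- spec_formula(spec)
  environment(fml) <- fit_env
  warns <- character(0)
  is_lmm <- spec$family == "GAUSSIAN" && spec$link == "IDENTITY"
  fit_call <- if (is_lmm) {
    call("lmer", fml, data = quote(.fit_data), REML = FALSE)
  } else {
    call("glmer", fml, data = quote(.fit_data), family = spec_family(spec),
         nAGQ = nAGQ)
  }
  fit_env$lmer <- lmerTest::lmer
  fit_env$glmer <- lme4::glmer
  fit <- withCallingHandlers(
    eval(fit_call, fit_env),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w)); invokeRestart("muffleWarning")
    },
    message = function(m) {
      warns <<- c(warns, trimws(conditionMessage(m))); invokeRestart("muffleMessage")
    }
  )
  # a singular (boundary) random-effect estimate is flagged in `warnings`
  # but is not a convergence failure
  conv_ok <- length(grep("converge|Hessian", warns, ignore.case = TRUE)) == 0L
  cf <- stats::coef(summary(fit))
  tests <- tryCatch({
    if (is_lmm) {
      a <- stats::anova(fit, type = 2)  # Satterthwaite F via lmerTest
      data.frame(term = rownames(a), statistic = a$`F value`,
                 df = a$NumDF, den_df = a$DenDF, p = a$`Pr(>F)`,
                 stringsAsFactors = FALSE)
    } else {
      a <- car::Anova(fit, type = 2)
      data.frame(term = rownames(a), statistic = a$Chisq, df = a$Df,
                 den_df = NA_real_, p = a$`Pr(>Chisq)`,
                 stringsAsFactors = FALSE)
    }
  }, error = function(e) NULL)
  structure(
    list(fit = fit, spec = spec, aic = stats::AIC(fit),
         converged = conv_ok,
         coefficients = data.frame(term = rownames(cf),
                                   estimate = cf[, "Estimate"],
                                   se = cf[, "Std. Error"],
                                   stringsAsFactors = FALSE),
         term_tests = tests,
         test_method = if (is_lmm) "Satterthwaite F" else "Wald chi-square",
         warnings = warns),
    class = "fit_result"
  )
}

#' Select the response family and link by AIC
#'
#' Fits every candidate family/link combination and returns the converged
#' candidate with the lowest AIC (ties broken by declared candidate
#' order, and logged in the AIC table).
#'
#' @param spec A `model_spec` (its family/link are ignored).
#' @param data Model data.
#' @param candidates data.frame with columns `family`, `link`.
#' @return List with `best_spec`, `best_fit`, `aic_table`.
#' @export
select_family <- function(spec, data,
                          candidates = data.frame(
                            family = c("INVERSE_GAUSSIAN", "GAMMA", "GAUSSIAN"),
                            link = c("IDENTITY", "IDENTITY", "IDENTITY"),
                            stringsAsFactors = FALSE)) {
  fits <- vector("list", nrow(candidates))
  aic <- rep(NA_real_, nrow(candidates))
  ok <- rep(FALSE, nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    cand <- model_spec(spec$response, spec$fixed, spec$random,
                       family = candidates$family[i], link = candidates$link[i])
    fits[[i]] <- tryCatch(fit_model(cand, data), error = function(e) NULL)
    if (!is.null(fits[[i]]) && fits[[i]]$converged) {
      ok[i] <- TRUE
      aic[i] <- fits[[i]]$aic
    }
  }
  if (!any(ok)) stop("no candidate family/link converged", call. = FALSE)
  tab <- cbind(candidates, aic = aic, converged = ok)
  best <- which(ok)[which.min(aic[ok])]
  tie <- ok & !is.na(aic) & aic == aic[best]
  list(best_spec = fits[[best]]$spec, best_fit = fits[[best]],
       aic_table = tab, tie = sum(tie) > 1L)
}

# terms that can be dropped while respecting marginality
removable_terms <- function(fixed) {
  keys <- lapply(fixed, function(tm) sort(strsplit(tm, ":", fixed = TRUE)[[1L]]))
  removable <- logical(length(fixed))
  for (i in seq_along(fixed)) {
    contained <- vapply(seq_along(fixed), function(j) {
      j != i && all(keys[[i]] %in% keys[[j]])
    }, logical(1L))
    removable[i] <- !any(contained)
  }
  fixed[removable]
}

#' Backward stepwise model reduction
#'
#' Iteratively removes the least-supported removable fixed-effect term
#' (one whose removal respects marginality) while the criterion favors
#' removal: for `"LRT"`, the term with the largest likelihood-ratio
#' p-value above `alpha` is dropped; for `"AIC"`, the removal with the
#' largest AIC improvement. Deterministic; the full removal trace is
#' returned.
#'
#' @param spec Initial `model_spec`.
#' @param data Model data.
#' @param criterion `"LRT"` (default) or `"AIC"`.
#' @param alpha Removal threshold for the LRT criterion.
#' @return List with `spec` (reduced), `fit` (a `fit_result`), `trace`
#'   (data.frame of steps).
#' @export
stepwise_backward <- function(spec, data, criterion = c("LRT", "AIC"),
                              alpha = 0.05) {
  criterion <- match.arg(criterion)
  current <- spec
  fit <- fit_model(current, data)
  trace <- list()
  repeat {
    cand <- removable_terms(current$fixed)
    if (length(cand) == 0L) break
    stats_tab <- lapply(cand, function(tm) {
      reduced <- current
      reduced$fixed <- setdiff(current$fixed, tm)
      rfit <- tryCatch(fit_model(reduced, data), error = function(e) NULL)
      if (is.null(rfit)) return(NULL)
      ll_full <- as.numeric(stats::logLik(fit$fit))
      ll_red <- as.numeric(stats::logLik(rfit$fit))
      df <- attr(stats::logLik(fit$fit), "df") - attr(stats::logLik(rfit$fit), "df")
      list(term = tm, fit = rfit,
           lrt_p = stats::pchisq(pmax(2 * (ll_full - ll_red), 0), df = max(df, 1),
                                 lower.tail = FALSE),
           delta_aic = rfit$aic - fit$aic)
    })
    stats_tab <- Filter(Negate(is.null), stats_tab)
    if (length(stats_tab) == 0L) break
    if (criterion == "LRT") {
      ps <- vapply(stats_tab, `[[`, numeric(1L), "lrt_p")
      k <- which.max(ps)
      drop_it <- ps[k] > alpha
    } else {
      das <- vapply(stats_tab, `[[`, numeric(1L), "delta_aic")
      k <- which.min(das)
      drop_it <- das[k] < 0
    }
    trace[[length(trace) + 1L]] <- data.frame(
      step = length(trace) + 1L, term = stats_tab[[k]]$term,
      lrt_p = stats_tab[[k]]$lrt_p, delta_aic = stats_tab[[k]]$delta_aic,
      removed = drop_it, stringsAsFactors = FALSE
    )
    if (!drop_it) break
    current$fixed <- setdiff(current$fixed, stats_tab[[k]]$term)
    fit <- stats_tab[[k]]$fit
  }
  list(spec = current, fit = fit,
       trace = if (length(trace)) do.call(rbind, trace) else
         data.frame(step = integer(), term = character(), lrt_p = numeric(),
                    delta_aic = numeric(), removed = logical()))
}

#' FDR-corrected pairwise contrasts
#'
#' Estimated marginal (cell) means over the crossing of the given
#' factors, all pairwise differences, Benjamini-Hochberg adjustment over
#' the contrast family.
#'
#' @param fitres A `fit_result`.
#' @param factors Character vector of factor names.
#' @param q FDR level.
#' @return data.frame with `contrast`, `estimate`, `se`, `statistic`,
#'   `p_raw`, `p_adj`, `reject`.
#' @export
pairwise_contrasts <- function(fitres, factors, q = 0.05) {
  mf <- stats::model.frame(fitres$fit)
  for (f in factors) {
    lv <- unique(as.character(mf[[f]]))
    if (length(lv) < 2L) {
      stop("factor `", f, "` has fewer than 2 levels", call. = FALSE)
    }
  }
  fml <- stats::as.formula(paste("~", paste(factors, collapse = " * ")))
  em <- emmeans::emmeans(fitres$fit, specs = fml)
  prs <- summary(emmeans::contrast(em, method = "pairwise", adjust = "none"))
  pcol <- if ("p.value" %in% names(prs)) "p.value" else "p"
  statcol <- intersect(c("t.ratio", "z.ratio"), names(prs))[1L]
  bh <- bh_fdr(prs[[pcol]], q = q)
  data.frame(
    contrast = as.character(prs$contrast),
    estimate = prs$estimate, se = prs$SE,
    statistic = prs[[statcol]],
    p_raw = prs[[pcol]], p_adj = bh$adjusted, reject = bh$reject,
    stringsAsFactors = FALSE
  )
}
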