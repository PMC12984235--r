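env_covariates <- function(env) {
  if (!is.data.frame(env)) stop("'env' must be a data frame")
  setdiff(names(env), "year")
}

vif_table <- function(env, vars) {
  # VIF_j = 1 / (1 - R^2_j), covariate j regressed on the other covariates
  vapply(vars, function(v) {
    fml <- as.formula(paste0("`", v, "` ~ ",
                             paste0("`", setdiff(vars, v), "`", collapse = " + ")))
    r2 <- suppressWarnings(summary(lm(fml, data = env))$r.squared)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
}

#' Iterative VIF screening of environmental covariates
#'
#' Computes variance inflation factors for every candidate covariate
#' (`1 / (1 - R^2)` from regressing it on all the others) and repeatedly
#' removes the covariate with the largest VIF while any VIF is at or above
#' the threshold. Perfectly collinear covariates get `Inf` and fall first.
#' The full audit trail (one VIF table per step) is retained.
#'
#' @param env Data frame with a `year` column and one column per covariate.
#' @param threshold Removal threshold (default 10).
#' @return Object of class `vif_report`: list with `steps` (each a list of
#'   `vif` table and `removed` name), `retained`, `threshold`.
#' @export
vif_screen <- function(env, threshold = 10) {
  vars <- env_covariates(env)
  if (length(vars) < 3) stop("VIF screening requires at least 3 covariates")
  steps <- list()
  repeat {
    if (nrow(env) <= length(vars))
      stop("fewer rows than covariates: VIFs are not identified")
    v <- vif_table(env, vars)
    if (max(v) < threshold) {
      steps[[length(steps) + 1]] <- list(vif = v, removed = NA_character_)
      break
    }
    worst <- names(v)[which.max(v)]
    steps[[length(steps) + 1]] <- list(vif = v, removed = worst)
    vars <- setdiff(vars, worst)
    if (length(vars) < 2) break
  }
  structure(list(steps = steps, retained = vars, threshold = threshold),
            class = "vif_report")
}

#' @export
print.vif_report <- function(x, ...) {
  for (i in seq_along(x$steps)) {
    s <- x$steps[[i]]
    cat(sprintf("step %d:%s\n", i,
                if (is.na(s$removed)) " (all VIF below threshold)"
                else paste0(" removed ", s$removed)))
    print(round(s$vif, 2))
  }
  cat("retained:", paste(x$retained, collapse = ", "), "\n")
  invisible(x)
}

build_gam_formula <- function(terms) {
  nm <- names(terms)
  if (is.null(nm) || any(nm == ""))
    stop("'terms' must be a named list/vector: covariate = basis dimension k")
  if (anyDuplicated(nm))
    stop(sprintf("aliased smooth terms: '%s' appears more than once",
                 nm[duplicated(nm)][1]))
  rhs <- paste(sprintf("s(%s, k = %d)", nm, as.integer(unlist(terms))),
               collapse = " + ")
  as.formula(paste("m ~", rhs))
}

#' Additive model of annual productivity on environmental covariates
#'
#' Penalized thin-plate regression splines with smoothing selected by REML
#' (via [mgcv::gam()]), relating the annual maximum net productivity series
#' from a time-varying fit to environmental covariates (and usually a year
#' smooth for background temporal structure).
#'
#' @param response Data frame with columns `year` and `m` (annual maximum
#'   net productivity, tonnes/yr), or a numeric vector aligned with `env`.
#' @param env Environmental table (data frame with `year` + covariates).
#' @param terms Named list/vector of basis dimensions, e.g.
#'   `list(year = 3, PDO = 9, MLT = 4)`. Each k must be at least 3 and
#'   less than the number of years.
#' @return Object of class `additive_fit`: the `mgcv` fit plus `aic`,
#'   `terms` (per-term edf and approximate p-value), and `curves`
#'   (per-term partial effects with pointwise 95% intervals).
#' @export
fit_additive_model <- function(response, env, terms) {
  if (is.data.frame(response)) {
    stopifnot(all(c("year", "m") %in% names(response)))
    dat <- merge(response, env, by = "year")
  } else {
    if (length(response) != nrow(env))
      stop("'response' length must match the environmental table")
    dat <- cbind(m = response, env)
  }
  nm <- names(terms)
  unknown <- setdiff(nm, names(dat))
  if (length(unknown))
    stop(sprintf("unknown covariate name: %s", paste(unknown, collapse = ", ")))
  k <- as.integer(unlist(terms))
  if (any(k < 3)) stop("each basis dimension k must be at least 3")
  if (any(k >= nrow(dat))) stop("basis dimension k must be less than the number of years")
  fml <- build_gam_formula(terms)
  g <- mgcv::gam(fml, data = dat, method = "REML")
  st <- summary(g)$s.table
  curves <- lapply(nm, function(v) {
    gridv <- seq(min(dat[[v]]), max(dat[[v]]), length.out = 100)
    nd <- dat[rep(1, 100), nm, drop = FALSE]
    for (w in nm) nd[[w]] <- mean(dat[[w]])
    nd[[v]] <- gridv
    pr <- predict(g, newdata = nd, type = "terms", se.fit = TRUE)
    cl <- grep(paste0("s\\(", v, "\\)"), colnames(pr$fit))
    data.frame(x = gridv, effect = pr$fit[, cl],
               lo = pr$fit[, cl] - 1.96 * pr$se.fit[, cl],
               hi = pr$fit[, cl] + 1.96 * pr$se.fit[, cl])
  })
  names(curves) <- nm
  structure(list(
    gam = g, formula = fml, aic = AIC(g),
    terms = data.frame(term = rownames(st), edf = st[, "edf"],
                       p_value = st[, "p-value"], row.names = NULL),
    curves = curves, data = dat
  ), class = "additive_fit")
}

#' @export
print.additive_fit <- function(x, ...) {
  cat(deparse(x$formula), "\n")
  cat(sprintf("AIC %.2f\n", x$aic))
  print(x$terms, digits = 3)
  invisible(x)
}

#' AIC selection over candidate environmental smooths
#'
#' Fits additive models for every subset of the candidate covariates (the
#' year smooth is always included) and returns the AIC ranking and the
#' minimum-AIC fit. With more than 8 candidates, greedy forward selection
#' is used instead of exhaustive search.
#'
#' @param response As in [fit_additive_model()].
#' @param env Environmental table; candidates should already be
#'   VIF-screened.
#' @param candidates Character vector of candidate covariate names.
#' @param k_default Basis dimension for covariate smooths (default 5).
#' @param k_year Basis dimension for the mandatory year smooth (default 3).
#' @param k Optional named overrides of basis dimensions.
#' @return List with `best` (an `additive_fit`), `ranking` (data frame of
#'   formulas and AIC, best first).
#' @export
select_model <- function(response, env, candidates,
                         k_default = 5, k_year = 3, k = list()) {
  if (anyDuplicated(candidates)) stop("duplicated candidate covariates")
  # refuse aliased candidate sets (identical columns)
  if (length(candidates) > 1) {
    cm <- suppressWarnings(cor(env[candidates]))
    cm[!is.finite(cm)] <- 0
    diag(cm) <- 0
    if (any(abs(cm) > 1 - 1e-10))
      stop("aliased candidates: two covariates are numerically identical; screen with vif_screen first")
  }
  kfor <- function(v) if (!is.null(k[[v]])) k[[v]] else k_default
  fit_subset <- function(sub) {
    terms <- c(list(year = k_year), setNames(lapply(sub, kfor), sub))
    fit_additive_model(response, env, terms)
  }
  if (length(candidates) <= 8) {
    subsets <- unlist(lapply(0:length(candidates), function(m)
      utils::combn(candidates, m, simplify = FALSE)), recursive = FALSE)
    fits <- lapply(subsets, fit_subset)
  } else {
    # forward selection
    current <- character(0)
    fits <- list(fit_subset(current))
    subsets <- list(current)
    repeat {
      remaining <- setdiff(candidates, current)
      if (!length(remaining)) break
      trial <- lapply(remaining, function(v) fit_subset(c(current, v)))
      aics <- vapply(trial, `[[`, numeric(1), "aic")
      best_i <- which.min(aics)
      if (aics[best_i] >= fits[[length(fits)]]$aic) break
      current <- c(current, remaining[best_i])
      fits[[length(fits) + 1]] <- trial[[best_i]]
      subsets[[length(subsets) + 1]] <- current
    }
  }
  aics <- vapply(fits, `[[`, numeric(1), "aic")
  ord <- order(aics)
  ranking <- data.frame(
    formula = vapply(fits, function(f) paste(deparse(f$formula), collapse = ""),
                     character(1)),
    covariates = vapply(subsets, paste, character(1), collapse = "+"),
    aic = aics
  )[ord, ]
  rownames(ranking) <- NULL
  list(best = fits[[ord[1]]], ranking = ranking)
}
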