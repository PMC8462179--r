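## Use-availability habitat-selection modelling.
##
## The response contrasts foraging dives (1) against pseudo-absences (0)
## in a binomial GAMM with logit link: smooth (cubic regression spline)
## effects of bathymetry, tidal current, distance to shore and least-cost
## distance to the last haulout, a categorical sediment effect whose
## reference level is forced to the over-represented class, and a
## ridge-penalized random intercept per individual (plus per site in
## global mode). Smoothing parameters are estimated by REML. Covariate
## importance is a drop-term explained-deviance decomposition.

.continuous_terms <- c("bathy", "tidal", "dist_shore", "dist_haulout")

#' Assemble the use-availability table
#'
#' @param dive_cov covariate rows of foraging dives (from
#'   [extract_covariates()]), with an `individual` column.
#' @param pa_cov covariate rows of pseudo-absences, same columns.
#' @param site site id (recycled), or per-row vector.
#' @return data.frame with `response` (1/0), covariates, `individual`,
#'   `site`; per-individual class counts logged.
#' @export
build_ua_table <- function(dive_cov, pa_cov, site = "site1") {
  cols <- c(.continuous_terms, "sediment", "individual")
  miss <- setdiff(cols, intersect(names(dive_cov), names(pa_cov)))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  d <- dive_cov[, cols, drop = FALSE]; d$response <- 1L
  a <- pa_cov[, cols, drop = FALSE]; a$response <- 0L
  tab <- rbind(d, a)
  tab$site <- rep_len(site, nrow(tab))
  bad <- setdiff(unique(d$individual), unique(a$individual))
  if (length(bad))
    stop("individual(s) without pseudo-absences: ", paste(bad, collapse = ", "))
  tab$individual <- factor(tab$individual)
  tab$site <- factor(tab$site)
  tab$sediment <- factor(tab$sediment)
  for (id in levels(tab$individual))
    ss_log("build_ua_table",
           sprintf("%s: %d used / %d available", id,
                   sum(tab$response == 1 & tab$individual == id),
                   sum(tab$response == 0 & tab$individual == id)))
  rownames(tab) <- NULL
  tab
}

#' Variance inflation factors of the continuous covariates
#'
#' `VIF_j = 1 / (1 - R^2_j)` from regressing covariate `j` on the other
#' continuous covariates plus dummy-coded sediment. Report-only: values
#' above the threshold raise a warning, perfectly collinear pairs report
#' `Inf` with a hard warning.
#'
#' @param table a [build_ua_table()] output.
#' @param terms continuous covariates to screen.
#' @param threshold warning threshold (default 5).
#' @return named numeric vector of VIFs.
#' @export
vif_screen <- function(table, terms = .continuous_terms, threshold = 5) {
  terms <- intersect(terms, names(table))
  if (length(terms) < 2L) stop("need >= 2 continuous covariates")
  has_sed <- "sediment" %in% names(table) && nlevels(factor(table$sediment)) > 1L
  out <- vapply(terms, function(tm) {
    rhs <- c(setdiff(terms, tm), if (has_sed) "sediment")
    f <- as.formula(paste(tm, "~", paste(rhs, collapse = " + ")))
    r2 <- suppressWarnings(summary(lm(f, data = table))$r.squared)
    if (r2 > 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  if (any(!is.finite(out)))
    warning("perfect collinearity detected: ",
            paste(terms[!is.finite(out)], collapse = ", "))
  else if (any(out > threshold))
    warning("VIF above ", threshold, ": ",
            paste(terms[out > threshold], collapse = ", "))
  out
}

## systematic 1-in-3 subsampling of dive rows (global mode); the dropped
## dives' pseudo-absences are dropped pro rata to keep the 1:2 balance
subsample_one_in_three <- function(table) {
  keep <- rep(TRUE, nrow(table))
  for (id in levels(table$individual)) {
    u <- which(table$response == 1 & table$individual == id)
    a <- which(table$response == 0 & table$individual == id)
    ku <- u[seq_along(u) %% 3L == 1L]
    ka <- a[seq_len(min(length(a), 2L * length(ku)))]
    keep[setdiff(u, ku)] <- FALSE
    keep[setdiff(a, ka)] <- FALSE
  }
  table[keep, , drop = FALSE]
}

#' Fit the smooth binomial selection model
#'
#' @param table a [build_ua_table()] output.
#' @param terms covariates to include (subset of the four continuous terms
#'   plus `"sediment"`).
#' @param k basis dimension of each cubic-regression-spline smooth.
#' @param mode `"colony"` (individual random intercept) or `"global"`
#'   (adds a site random intercept and applies 1-in-3 dive subsampling
#'   unless `subsample = "none"`).
#' @param subsample `"none"` or `"one_in_three"` (default follows mode).
#' @param linear terms to enter linearly instead of as smooths.
#' @param shrink use shrinkage smooths (`bs = "cs"`), whose penalty can
#'   remove a term entirely; the default plain `"cr"` basis leaves the
#'   linear null space unpenalized. [select_model()] fits its candidates
#'   with shrinkage so that AIC comparison is not dominated by null-space
#'   noise.
#' @param reference_sediment reference level; default forces the
#'   over-represented (modal) sediment class.
#' @param seed integer; stamps the fit (the REML fit itself is
#'   deterministic given the data).
#' @return object of class `selection_model`.
#' @export
fit_selection_model <- function(table,
                                terms = c(.continuous_terms, "sediment"),
                                k = 5, mode = c("colony", "global"),
                                subsample = NULL, linear = character(0),
                                reference_sediment = NULL, seed = NULL,
                                shrink = FALSE) {
  mode <- match.arg(mode)
  subsample <- subsample %||% (if (mode == "global") "one_in_three" else "none")
  if (subsample == "one_in_three") table <- subsample_one_in_three(table)
  table <- droplevels(table)

  if ("sediment" %in% terms) {
    ref <- reference_sediment %||%
      names(which.max(table(table$sediment)))
    table$sediment <- stats::relevel(table$sediment, ref = ref)
  }
  sm <- setdiff(intersect(terms, .continuous_terms), linear)
  lin <- c(intersect(linear, terms),
           if ("sediment" %in% terms && nlevels(table$sediment) > 1L) "sediment")
  bs <- if (shrink) "cs" else "cr"
  parts <- c(
    sprintf("s(%s, bs = \"%s\", k = %d)", sm, bs, k),
    lin,
    if (nlevels(table$individual) > 1L) "s(individual, bs = \"re\")",
    if (mode == "global" && nlevels(table$site) > 1L) "s(site, bs = \"re\")")
  if (!length(parts)) parts <- "1"
  f <- as.formula(paste("response ~", paste(parts, collapse = " + ")))
  fit <- try(mgcv::gam(f, data = table, family = binomial(link = "logit"),
                       method = "REML", select = FALSE), silent = TRUE)
  if (inherits(fit, "try-error") || !fit$converged)
    stop("selection model did not converge: ",
         if (inherits(fit, "try-error")) attr(fit, "condition")$message
         else "IRLS/REML iteration limit")
  rng <- lapply(table[intersect(terms, .continuous_terms)], range)
  structure(list(
    fit = fit, terms = terms, k = k, mode = mode, subsample = subsample,
    linear = linear, shrink = shrink, seed = seed, n = nrow(table),
    reference_sediment = if ("sediment" %in% terms)
      levels(table$sediment)[1] else NA,
    covariate_ranges = rng,
    aic = AIC(fit),
    explained_deviance = 100 * (1 - fit$deviance / fit$null.deviance)),
    class = "selection_model")
}

#' @export
print.selection_model <- function(x, ...) {
  cat(sprintf("<selection_model> %s mode, n = %d, terms: %s\n",
              x$mode, x$n, paste(x$terms, collapse = ", ")))
  cat(sprintf("  AIC %.2f, explained deviance %.1f%%\n",
              x$aic, x$explained_deviance))
  invisible(x)
}

#' Explained deviance of a fitted selection model
#'
#' `100 * (1 - D_model / D_null)`, in percent.
#'
#' @param model a [fit_selection_model()] object or an mgcv fit.
#' @return percentage in \[0, 100\].
#' @export
explained_deviance <- function(model) {
  fit <- if (inherits(model, "selection_model")) model$fit else model
  100 * (1 - fit$deviance / fit$null.deviance)
}

#' AIC model selection over candidate term sets
#'
#' Fits each candidate (default: all non-empty subsets of the supplied
#' terms) and returns the minimal-AIC model together with the full AIC
#' ledger. AIC uses the effective degrees of freedom of the penalized
#' terms. Ties (within 1e-8) break toward fewer terms; failed candidates
#' are recorded and selection proceeds over the survivors.
#'
#' @param table a [build_ua_table()] output.
#' @param candidates list of character vectors of terms; default all
#'   subsets of `terms`.
#' @param terms the full term set for the default candidate list.
#' @param shrink fit candidates with shrinkage smooths (default TRUE).
#' @param ... passed to [fit_selection_model()].
#' @return list of class `model_selection`: `best` (a selection_model),
#'   `ledger` (data.frame terms/AIC/ED/dAIC/error).
#' @export
select_model <- function(table, candidates = NULL,
                         terms = c(.continuous_terms, "sediment"),
                         shrink = TRUE, ...) {
  if (is.null(candidates)) {
    candidates <- unlist(lapply(seq_along(terms), function(m)
      combn(terms, m, simplify = FALSE)), recursive = FALSE)
  }
  if (length(candidates) < 2L) stop("need >= 2 candidate term sets")
  fits <- lapply(candidates, function(tm)
    try(fit_selection_model(table, terms = tm, shrink = shrink, ...),
        silent = TRUE))
  ok <- !vapply(fits, inherits, logical(1), "try-error")
  if (!any(ok)) stop("all candidate fits failed")
  led <- data.frame(
    terms = vapply(candidates, paste, character(1), collapse = "+"),
    n_terms = lengths(candidates),
    aic = ifelse(ok, vapply(fits, function(f)
      if (inherits(f, "try-error")) NA_real_ else f$aic, numeric(1)), NA_real_),
    ed = vapply(fits, function(f)
      if (inherits(f, "try-error")) NA_real_ else f$explained_deviance,
      numeric(1)),
    error = !ok)
  best_aic <- min(led$aic, na.rm = TRUE)
  cand <- which(!is.na(led$aic) & led$aic <= best_aic + 1e-8)
  best <- cand[which.min(led$n_terms[cand])]
  led$dAIC <- led$aic - led$aic[best]
  structure(list(best = fits[[best]], ledger = led[order(led$aic), ]),
            class = "model_selection")
}

#' Drop-term covariate importance (% of explained deviance)
#'
#' Refits the model with each covariate dropped in turn; a term's raw
#' importance is the loss of explained deviance, negative losses are
#' floored at zero (and logged), and shares are normalized to sum 100%.
#' Random-effect terms are not part of the decomposition.
#'
#' @param model a [fit_selection_model()] object.
#' @param table the table it was fitted on.
#' @return named numeric vector of percentage shares (sums to 100).
#' @export
term_importance <- function(model, table) {
  terms <- model$terms
  if (length(terms) == 1L)
    return(setNames(100, terms))
  ed_full <- model$explained_deviance
  raw <- vapply(terms, function(tm) {
    ref <- try(fit_selection_model(
      table, terms = setdiff(terms, tm), k = model$k, mode = model$mode,
      subsample = "none", linear = model$linear, shrink = model$shrink,
      reference_sediment = if ("sediment" %in% setdiff(terms, tm))
        model$reference_sediment else NULL), silent = TRUE)
    if (inherits(ref, "try-error")) return(NA_real_)
    ed_full - ref$explained_deviance
  }, numeric(1))
  if (any(is.na(raw)))
    ss_log("term_importance", sprintf("refit failed for: %s",
                                      paste(terms[is.na(raw)], collapse = ", ")))
  if (any(raw < 0, na.rm = TRUE))
    ss_log("term_importance",
           sprintf("negative drop floored at 0 for: %s",
                   paste(terms[which(raw < 0)], collapse = ", ")))
  raw[!is.na(raw) & raw < 0] <- 0
  tot <- sum(raw, na.rm = TRUE)
  shares <- if (tot > 0) 100 * raw / tot else
    100 * as.numeric(!is.na(raw)) / sum(!is.na(raw))
  setNames(shares, terms)
}

#' Predict a habitat-selection map over the seascape
#'
#' Population-level inverse-logit predictions on every sea cell (random
#' intercepts set to zero), with approximate pointwise standard errors on
#' the link scale and a per-cell extrapolation flag where a covariate
#' leaves the fitted range. The distance-to-last-haulout covariate is
#' mapped as the least-cost distance to the nearest colony haulout.
#'
#' @param model a [fit_selection_model()] object.
#' @param seascape a [make_seascape()] object.
#' @param seagraph optional pre-built [build_sea_graph()].
#' @return list of [sea_grid()]s: `prob` (selection probability in
#'   \[0, 1\]), `se_link`, `extrapolated` (0/1).
#' @export
predict_map <- function(model, seascape, seagraph = NULL) {
  seagraph <- seagraph %||% build_sea_graph(seascape)
  cov <- sea_cell_covariates(seascape, seagraph)
  nd <- data.frame(bathy = cov$bathy, tidal = cov$tidal,
                   dist_shore = cov$dist_shore,
                   dist_haulout = cov$dist_haulout,
                   sediment = factor(paste0("sed", cov$sediment)))
  fit <- model$fit
  ## unseen sediment classes cannot be predicted; map them to the reference
  lev <- levels(fit$model$sediment)
  if (!is.null(lev)) {
    unseen <- !(as.character(nd$sediment) %in% lev)
    nd$sediment <- factor(ifelse(unseen, lev[1], as.character(nd$sediment)),
                          levels = lev)
  }
  nd$individual <- factor(levels(fit$model$individual)[1],
                          levels = levels(fit$model$individual))
  if (!is.null(fit$model$site))
    nd$site <- factor(levels(fit$model$site)[1],
                      levels = levels(fit$model$site))
  excl <- grep("^s\\((individual|site)\\)$",
               vapply(fit$smooth, function(s) s$label, character(1)),
               value = TRUE)
  ok <- is.finite(nd$dist_haulout)
  pr <- predict(fit, newdata = nd[ok, , drop = FALSE], type = "link",
                se.fit = TRUE, exclude = excl, newdata.guaranteed = TRUE)
  extrap <- rep(FALSE, nrow(nd))
  for (tm in intersect(model$terms, names(model$covariate_ranges))) {
    rg <- model$covariate_ranges[[tm]]
    extrap <- extrap | nd[[tm]] < rg[1] | nd[[tm]] > rg[2]
  }
  mk <- function(vals) {
    m <- matrix(NA_real_, seascape$bathy$ny, seascape$bathy$nx)
    m[cbind(cov$row[ok], cov$col[ok])] <- vals
    sea_grid(m, 0, 0, seascape$bathy$cellsize)
  }
  list(prob = mk(1 / (1 + exp(-as.numeric(pr$fit)))),
       se_link = mk(as.numeric(pr$se.fit)),
       extrapolated = mk(as.numeric(extrap[ok])))
}
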