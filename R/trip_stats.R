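## Group comparisons of trip metrics across colonies and the mixed-model
## test of colony-size and latitude effects.
##
## Trip duration and maximum extent are log-transformed; Shapiro-Wilk
## (per site) and Bartlett (across sites) gate the parametric branch at
## alpha = 0.05. The parametric branch is one-way ANOVA with Tukey HSD
## post hocs, the nonparametric branch Kruskal-Wallis with Dunn's pairwise
## rank test (tie-corrected z statistics, Holm-adjusted by default).

#' Build the trip-metrics table
#'
#' @param trips trip table with `seal`, `duration_h`, `max_extent_km`.
#' @param site site id (recycled or per-row).
#' @param species species label.
#' @param n_seals_at_colony,latitude site covariates (constant per site).
#' @return data.frame with log-transformed metrics added.
#' @export
trip_metrics_table <- function(trips, site = "site1", species = "gray",
                               n_seals_at_colony = NA, latitude = NA) {
  stopifnot(all(trips$duration_h > 0), all(trips$max_extent_km > 0))
  data.frame(seal = trips$seal, site = rep_len(site, nrow(trips)),
             species = rep_len(species, nrow(trips)),
             duration_h = trips$duration_h,
             max_extent_km = trips$max_extent_km,
             log_duration = log(trips$duration_h),
             log_extent = log(trips$max_extent_km),
             n_seals = rep_len(n_seals_at_colony, nrow(trips)),
             latitude = rep_len(latitude, nrow(trips)))
}

#' Normality and homoscedasticity gate
#'
#' Shapiro-Wilk per site and Bartlett across sites on the chosen metric;
#' the parametric branch is taken when no test rejects at `alpha`.
#' Sites with fewer than 3 trips are skipped with a log entry.
#'
#' @param table a [trip_metrics_table()].
#' @param metric column name (e.g. `"log_duration"`).
#' @param alpha gate level.
#' @return list: `shapiro` (named p-values), `bartlett_p`, `branch`
#'   (`"parametric"` or `"nonparametric"`).
#' @export
assumption_tests <- function(table, metric = "log_duration", alpha = 0.05) {
  v <- table[[metric]]
  groups <- split(v, table$site)
  sizes <- vapply(groups, length, integer(1))
  small <- names(groups)[sizes < 3L]
  if (length(small))
    ss_log("assumption_tests",
           sprintf("site(s) skipped (n < 3): %s", paste(small, collapse = ", ")))
  groups <- groups[sizes >= 3L]
  if (length(groups) < 2L) stop("Bartlett test undefined with < 2 usable sites")
  sh <- vapply(groups, function(g)
    shapiro.test(if (length(g) > 5000) sample(g, 5000) else g)$p.value,
    numeric(1))
  bt <- bartlett.test(groups)$p.value
  branch <- if (all(sh > alpha) && bt > alpha) "parametric" else "nonparametric"
  list(shapiro = sh, bartlett_p = bt, branch = branch)
}

#' Dunn's pairwise rank test after Kruskal-Wallis
#'
#' Pairwise z statistics on mean joint ranks with tie correction,
#' two-sided p-values and multiplicity adjustment.
#'
#' @param v numeric values.
#' @param g grouping factor.
#' @param method p-adjustment method (default `"holm"`).
#' @return data.frame `a`, `b`, `z`, `p`, `p_adj`.
#' @export
dunn_test <- function(v, g, method = "holm") {
  g <- factor(g)
  r <- rank(v)
  N <- length(v)
  ties <- table(r)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  rbar <- tapply(r, g, mean)
  ns <- tapply(r, g, length)
  prs <- combn(levels(g), 2L, simplify = FALSE)
  out <- lapply(prs, function(ab) {
    i <- ab[1]; j <- ab[2]
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / ns[[i]] + 1 / ns[[j]]))
    z <- (rbar[[i]] - rbar[[j]]) / se
    data.frame(a = i, b = j, z = z, p = 2 * pnorm(-abs(z)))
  })
  out <- do.call(rbind, out)
  out$p_adj <- p.adjust(out$p, method = method)
  rownames(out) <- NULL
  out
}

#' Compare a trip metric across sites
#'
#' Parametric branch: one-way ANOVA with Tukey HSD post hocs.
#' Nonparametric branch: Kruskal-Wallis with Dunn's pairwise test
#' (Holm-adjusted). The branch defaults to the [assumption_tests()] gate.
#'
#' @param table a [trip_metrics_table()].
#' @param metric column name.
#' @param branch `"auto"`, `"parametric"` or `"nonparametric"`.
#' @param posthoc compute the pairwise table (default TRUE).
#' @param p_adjust_method Dunn adjustment method.
#' @return list of class `site_comparison`: `branch`, `statistic`, `df`,
#'   `p`, `pairwise` (data.frame or NULL).
#' @export
compare_sites <- function(table, metric = "log_duration",
                          branch = c("auto", "parametric", "nonparametric"),
                          posthoc = TRUE, p_adjust_method = "holm") {
  branch <- match.arg(branch)
  if (length(unique(table$site)) < 2L) stop("need >= 2 sites")
  if (branch == "auto")
    branch <- assumption_tests(table, metric)$branch
  v <- table[[metric]]; g <- factor(table$site)
  if (branch == "parametric") {
    fit <- aov(v ~ g)
    an <- summary(fit)[[1]]
    pw <- NULL
    if (posthoc) {
      tk <- TukeyHSD(fit)$g
      pw <- data.frame(a = sub("-.*", "", rownames(tk)),
                       b = sub(".*-", "", rownames(tk)),
                       diff = tk[, "diff"], p_adj = tk[, "p adj"])
      rownames(pw) <- NULL
    }
    out <- list(branch = branch, statistic = an$`F value`[1],
                df = an$Df[1], p = an$`Pr(>F)`[1], pairwise = pw)
  } else {
    kw <- kruskal.test(v, g)
    pw <- if (posthoc) dunn_test(v, g, method = p_adjust_method) else NULL
    out <- list(branch = branch, statistic = unname(kw$statistic),
                df = unname(kw$parameter), p = kw$p.value, pairwise = pw)
  }
  structure(out, class = "site_comparison")
}

#' @export
print.site_comparison <- function(x, ...) {
  cat(sprintf("<site_comparison> %s: statistic %.3f (df %d), p = %.4g\n",
              x$branch, x$statistic, x$df, x$p))
  if (!is.null(x$pairwise))
    cat(sprintf("  %d pairwise contrasts, %d significant at 0.05\n",
                nrow(x$pairwise), sum(x$pairwise$p_adj < 0.05)))
  invisible(x)
}

#' Colony-size / latitude mixed models of a trip metric
#'
#' Fits the three candidate linear mixed models of a log trip metric -
#' colony seal count + site random intercept, latitude + site random
#' intercept, and both - by maximum likelihood (for AIC comparability),
#' returns the AIC ledger, the winner, and Wald p-values of its fixed
#' effects. Singular random-effect fits are recorded but retained.
#'
#' @param table a [trip_metrics_table()] (pooled across >= 4 sites).
#' @param metric `"log_duration"` or `"log_extent"`.
#' @return list of class `colony_size_models`: `ledger`, `best` (an lme
#'   fit), `best_name`, `fixed_p` (named Wald p-values).
#' @export
colony_size_models <- function(table, metric = "log_duration") {
  if (length(unique(table$site)) < 4L) stop("need >= 4 sites")
  dat <- data.frame(y = table[[metric]], n_seals = table$n_seals,
                    latitude = table$latitude, site = factor(table$site))
  forms <- list(n_seals = y ~ n_seals,
                latitude = y ~ latitude,
                n_seals_latitude = y ~ n_seals + latitude)
  fits <- lapply(forms, function(f) {
    ft <- try(nlme::lme(f, random = ~ 1 | site, data = dat, method = "ML"),
              silent = TRUE)
    if (inherits(ft, "try-error"))
      ss_log("colony_size_models", paste("candidate failed:", deparse(f)))
    ft
  })
  ok <- !vapply(fits, inherits, logical(1), "try-error")
  if (!any(ok)) stop("all mixed-model candidates failed")
  aics <- ifelse(ok, vapply(fits, function(f)
    if (inherits(f, "try-error")) NA_real_ else AIC(f), numeric(1)), NA_real_)
  ledger <- data.frame(model = names(forms), aic = aics,
                       dAIC = aics - min(aics, na.rm = TRUE))
  best <- which.min(aics)
  tt <- summary(fits[[best]])$tTable
  fx <- setdiff(rownames(tt), "(Intercept)")
  structure(list(ledger = ledger, best = fits[[best]],
                 best_name = names(forms)[best],
                 fixed_p = setNames(tt[fx, "p-value"], fx)),
            class = "colony_size_models")
}

#' @export
print.colony_size_models <- function(x, ...) {
  cat("<colony_size_models> AIC ledger:\n")
  print(x$ledger, row.names = FALSE)
  cat(sprintf("  winner: %s; fixed-effect p: %s\n", x$best_name,
              paste(sprintf("%s = %.3g", names(x$fixed_p), x$fixed_p),
                    collapse = ", ")))
  invisible(x)
}
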