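#' Relative cell viability: normalize treatment arms to the untreated control
#'
#' Divides every measurement by the mean of the untreated arm, optionally
#' within plate/condition groupings, so the untreated arm has mean 1.
#'
#' @param data Data frame of raw viability measurements.
#' @param value Measurement column (unquoted).
#' @param treatment Treatment-label column (unquoted).
#' @param untreated_label Level of `treatment` identifying the untreated
#'   control.
#' @param by Optional character vector of columns defining independent
#'   normalization groups (e.g. plate, cell line).
#' @return The input tibble with an added `relative_viability` column.
#' @export
relative_viability <- function(data, value, treatment,
                               untreated_label = "untreated", by = NULL) {
  value <- rlang::enquo(value); treatment <- rlang::enquo(treatment)
  data <- tibble::as_tibble(data)
  out <- if (is.null(by)) data else
    dplyr::group_by(data, dplyr::across(dplyr::all_of(by)))
  out <- dplyr::mutate(
    out, .ctrl = mean((!!value)[(!!treatment) == untreated_label])
  )
  out <- dplyr::ungroup(out)
  if (anyNA(out$.ctrl) || any(is.nan(out$.ctrl)) || any(out$.ctrl <= 0)) {
    abort("Untreated arm missing or has non-positive mean; cannot normalize.")
  }
  out$relative_viability <- dplyr::pull(out, !!value) / out$.ctrl
  out$.ctrl <- NULL
  out
}

# ---- four-parameter logistic dose-response -------------------------------

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of `response = bottom + (top - bottom) /
#' (1 + (dose / ic50)^hill)` on log10 dose, with multi-start initialization
#' of the IC50 over the observed dose range to avoid local minima. At
#' `dose = ic50` the fitted response is `(top + bottom) / 2` by construction.
#'
#' @param data Data frame of dose-response measurements.
#' @param dose Dose column (unquoted), strictly positive.
#' @param response Response column (unquoted), non-negative.
#' @return An object of class `fit_4pl`: list with `coefficients` (named
#'   `top`, `bottom`, `ic50`, `hill`), `std_errors` (same names; delta-method
#'   for `ic50`), `converged`, `diagnostic` (`"ok"`, `"flat_response"`,
#'   `"no_convergence"`, or `"ic50_outside_dose_range"`), `rss`, `data`.
#'   Methods: [generics::tidy()], [generics::glance()], `predict`,
#'   [ggplot2::autoplot()].
#' @export
fit_4pl <- function(data, dose = dose, response = viability) {
  dose <- rlang::enquo(dose); response <- rlang::enquo(response)
  d <- dplyr::pull(data, !!dose); r <- dplyr::pull(data, !!response)
  if (any(d <= 0)) abort("Doses must be strictly positive.")
  if (any(r < 0)) abort("Responses must be non-negative.")
  if (length(unique(d)) < 4L) abort("Need at least 4 distinct doses for a 4PL fit.")
  df <- tibble::tibble(dose = d, response = r, l10d = log10(d))

  base <- list(coefficients = c(top = NA_real_, bottom = NA_real_,
                                ic50 = NA_real_, hill = NA_real_),
               std_errors = c(top = NA_real_, bottom = NA_real_,
                              ic50 = NA_real_, hill = NA_real_),
               converged = FALSE, diagnostic = "ok", rss = NA_real_,
               n = nrow(df), data = df, model = NULL)
  if (sd(r) == 0) {
    base$diagnostic <- "flat_response"
    return(structure(base, class = "fit_4pl"))
  }

  starts_l10 <- quantile(df$l10d, c(0.15, 0.35, 0.5, 0.65, 0.85), names = FALSE)
  fits <- list()
  for (s in starts_l10) {
    for (h0 in c(0.7, 1.5)) {
      f <- tryCatch(
        minpack.lm::nlsLM(
          response ~ bottom + (top - bottom) / (1 + 10^(hill * (l10d - l10ic50))),
          data = df,
          start = list(top = max(r), bottom = min(r), l10ic50 = s, hill = h0),
          lower = c(top = -Inf, bottom = -Inf, l10ic50 = -Inf, hill = 1e-3),
          control = minpack.lm::nls.lm.control(maxiter = 200)
        ),
        error = function(e) NULL, warning = function(w) NULL
      )
      if (!is.null(f)) fits[[length(fits) + 1L]] <- f
    }
  }
  if (!length(fits)) {
    base$diagnostic <- "no_convergence"
    return(structure(base, class = "fit_4pl"))
  }
  rss <- vapply(fits, function(f) sum(resid(f)^2), 0)
  best <- fits[[which.min(rss)]]
  cf <- coef(best)
  se <- tryCatch(sqrt(diag(vcov(best))), error = function(e) rep(NA_real_, 4L))
  names(se) <- names(cf)
  ic50 <- 10^cf[["l10ic50"]]
  out <- base
  out$coefficients <- c(top = cf[["top"]], bottom = cf[["bottom"]],
                        ic50 = ic50, hill = cf[["hill"]])
  out$std_errors <- c(top = se[["top"]], bottom = se[["bottom"]],
                      ic50 = log(10) * ic50 * se[["l10ic50"]],
                      hill = se[["hill"]])
  out$converged <- TRUE
  out$rss <- min(rss)
  out$model <- best
  rng <- range(df$l10d)
  if (cf[["l10ic50"]] < rng[1] - 0.5 || cf[["l10ic50"]] > rng[2] + 0.5) {
    out$diagnostic <- "ic50_outside_dose_range"
  }
  structure(out, class = "fit_4pl")
}

#' @export
print.fit_4pl <- function(x, ...) {
  if (!x$converged) {
    cat(sprintf("<fit_4pl> not converged (%s)\n", x$diagnostic))
    return(invisible(x))
  }
  cf <- x$coefficients
  cat(sprintf(
    "<fit_4pl> IC50 = %.4g, hill = %.3g, top = %.3g, bottom = %.3g (RSS %.4g%s)\n",
    cf[["ic50"]], cf[["hill"]], cf[["top"]], cf[["bottom"]], x$rss,
    if (x$diagnostic != "ok") paste0("; ", x$diagnostic) else ""))
  invisible(x)
}

#' @export
predict.fit_4pl <- function(object, newdata = NULL, ...) {
  if (!object$converged) abort("Cannot predict from an unconverged 4PL fit.")
  d <- if (is.null(newdata)) object$data$dose else
    if (is.numeric(newdata)) newdata else newdata$dose
  cf <- object$coefficients
  four_pl(d, cf[["top"]], cf[["bottom"]], cf[["ic50"]], cf[["hill"]])
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.fit_4pl <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients),
                 std.error = unname(x$std_errors))
}

#' @export
glance.fit_4pl <- function(x, ...) {
  tibble::tibble(converged = x$converged, diagnostic = x$diagnostic,
                 rss = x$rss, n = x$n,
                 sigma = if (x$converged) sqrt(x$rss / max(x$n - 4L, 1L)) else NA_real_)
}

# ---- ANOVA and multiple-comparison families ------------------------------

group_summaries <- function(value, group) {
  group <- as.character(group)
  if (anyNA(value) || anyNA(group)) abort("Missing values in `value` or `group`.")
  spl <- split(value, group)
  if (length(spl) < 2L) abort("Need at least 2 groups.")
  ns <- vapply(spl, length, 0L)
  if (any(ns < 2L)) abort("Every group needs at least 2 observations.")
  means <- vapply(spl, mean, 0)
  ss_within <- sum(vapply(spl, function(x) sum((x - mean(x))^2), 0))
  N <- sum(ns); k <- length(spl)
  list(levels = names(spl), n = ns, means = means, N = N, k = k,
       df_within = N - k, ss_within = ss_within,
       mse = ss_within / (N - k),
       grand = mean(value),
       ss_between = sum(ns * (means - mean(value))^2))
}

#' One-way analysis of variance
#'
#' Standard between/within sums-of-squares decomposition. With zero
#' within-group variance and a non-zero between-group difference the F
#' statistic is reported as `Inf` with p = 0.
#'
#' @param data Data frame of observations.
#' @param value Response column (unquoted).
#' @param group Group-label column (unquoted).
#' @return A tibble with rows for the group term and residuals: `term`,
#'   `df`, `sumsq`, `meansq`, `statistic`, `p.value`.
#' @export
one_way_anova <- function(data, value, group) {
  value <- rlang::enquo(value); group <- rlang::enquo(group)
  g <- group_summaries(dplyr::pull(data, !!value),
                       dplyr::pull(data, !!group))
  ms_b <- g$ss_between / (g$k - 1)
  f <- if (g$mse == 0) {
    if (ms_b == 0) 0 else Inf
  } else ms_b / g$mse
  p <- if (is.infinite(f)) 0 else stats::pf(f, g$k - 1, g$df_within, lower.tail = FALSE)
  tibble::tibble(
    term = c("group", "Residuals"),
    df = c(g$k - 1, g$df_within),
    sumsq = c(g$ss_between, g$ss_within),
    meansq = c(ms_b, g$mse),
    statistic = c(f, NA_real_),
    p.value = c(p, NA_real_)
  )
}

new_comparison_family <- function(test, comparisons, omnibus, df_residual, mse) {
  comparisons$stars <- significance_tiers(comparisons$adj.p.value)
  structure(list(test = test, comparisons = comparisons, omnibus = omnibus,
                 df_residual = df_residual, mse = mse),
            class = "comparison_family")
}

#' @export
print.comparison_family <- function(x, ...) {
  cat(sprintf("<comparison_family> %s, %d comparison(s), residual df %d\n",
              x$test, nrow(x$comparisons), x$df_residual))
  print(x$comparisons)
  invisible(x)
}

#' @export
tidy.comparison_family <- function(x, ...) x$comparisons

#' @export
glance.comparison_family <- function(x, ...) {
  om <- x$omnibus[!is.na(x$omnibus$statistic), ]
  tibble::tibble(test = x$test, n_comparisons = nrow(x$comparisons),
                 df_residual = x$df_residual, mse = x$mse,
                 statistic = om$statistic[1], p.value = om$p.value[1])
}

#' Dunnett's many-to-one comparisons against a control
#'
#' Each group is compared with the designated control using the pooled
#' within-group error from the one-way layout; familywise-adjusted two-sided
#' p-values come from the equicorrelated multivariate t distribution with
#' correlations determined by the group sizes, evaluated with
#' [mvtnorm::pmvt()] under a fixed internal seed so results are
#' reproducible.
#'
#' @param data Data frame of observations.
#' @param value Response column (unquoted).
#' @param group Group-label column (unquoted).
#' @param control Label of the control group.
#' @return A `comparison_family` (test `"one_way_dunnett"`): use
#'   [generics::tidy()] for the per-comparison table (estimate, unadjusted
#'   and adjusted p, significance stars) and [generics::glance()] for the
#'   omnibus F.
#' @export
dunnett <- function(data, value, group, control) {
  value <- rlang::enquo(value); group <- rlang::enquo(group)
  v <- dplyr::pull(data, !!value); gl <- as.character(dplyr::pull(data, !!group))
  g <- group_summaries(v, gl)
  if (!control %in% g$levels) {
    abort(sprintf("Control group '%s' not present (groups: %s).",
                  control, paste(g$levels, collapse = ", ")))
  }
  others <- setdiff(g$levels, control)
  n0 <- g$n[[control]]
  est <- g$means[others] - g$means[[control]]
  se <- sqrt(g$mse * (1 / g$n[others] + 1 / n0))
  tstat <- ifelse(se > 0, est / se, ifelse(est == 0, 0, Inf * sign(est)))
  lambda <- g$n[others] / (g$n[others] + n0)
  m <- length(others)
  corr <- sqrt(outer(lambda, lambda)); diag(corr) <- 1
  adj <- vapply(seq_len(m), function(i) {
    t_i <- abs(tstat[i])
    if (!is.finite(t_i)) return(0)
    if (t_i == 0) return(1)
    prob <- with_preserved_seed(20240601, mvtnorm::pmvt(
      lower = rep(-t_i, m), upper = rep(t_i, m), df = g$df_within,
      corr = corr, algorithm = mvtnorm::GenzBretz(abseps = 1e-4, maxpts = 25000L)
    ))
    min(max(1 - as.numeric(prob), 0), 1)
  }, 0)
  unadj <- ifelse(is.finite(tstat), 2 * pt(-abs(tstat), g$df_within),
                  ifelse(tstat == 0, 1, 0))
  comparisons <- tibble::tibble(
    comparison = paste(others, "-", control),
    estimate = unname(est), std.error = unname(se),
    statistic = unname(tstat), df = g$df_within,
    p.value = unname(unadj), adj.p.value = pmax(unname(adj), unname(unadj))
  )
  omnibus <- one_way_anova(tibble::tibble(v = v, g = gl), v, g)
  new_comparison_family("one_way_dunnett", comparisons, omnibus,
                        g$df_within, g$mse)
}

#' Tukey's honestly-significant-difference all-pairs comparisons
#'
#' All pairwise group differences on the pooled one-way error, with
#' familywise-adjusted p-values from the studentized range distribution
#' (Tukey-Kramer for unequal group sizes).
#'
#' @inheritParams dunnett
#' @return A `comparison_family` (test `"one_way_tukey"`).
#' @export
tukey_hsd <- function(data, value, group) {
  value <- rlang::enquo(value); group <- rlang::enquo(group)
  v <- dplyr::pull(data, !!value); gl <- as.character(dplyr::pull(data, !!group))
  g <- group_summaries(v, gl)
  pairs <- utils::combn(g$levels, 2L)
  comparisons <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    est <- g$means[[b]] - g$means[[a]]
    se <- sqrt(g$mse * (1 / g$n[[a]] + 1 / g$n[[b]]))
    tstat <- if (se > 0) est / se else if (est == 0) 0 else Inf * sign(est)
    q <- sqrt(2) * abs(tstat)
    padj <- if (!is.finite(q)) 0 else
      ptukey(q, nmeans = g$k, df = g$df_within, lower.tail = FALSE)
    punadj <- if (is.finite(tstat)) 2 * pt(-abs(tstat), g$df_within) else
      if (tstat == 0) 1 else 0
    tibble::tibble(comparison = paste(b, "-", a), estimate = est,
                   std.error = se, statistic = tstat, df = g$df_within,
                   p.value = punadj, adj.p.value = max(padj, punadj))
  })
  omnibus <- one_way_anova(tibble::tibble(v = v, g = gl), v, g)
  new_comparison_family("one_way_tukey", comparisons, omnibus,
                        g$df_within, g$mse)
}

#' Two-way ANOVA with Tukey comparisons on one factor
#'
#' Fits the two-factor model with interaction, reports type II sums of
#' squares for the main effects and the interaction (on balanced designs
#' type I, II and III coincide; unbalanced input triggers a warning naming
#' the convention), then runs Tukey all-pairs comparisons on the marginal
#' means of `tukey_on` using the full-model residual error.
#'
#' @param data Data frame of observations.
#' @param value Response column (unquoted).
#' @param factor_a,factor_b Factor columns (unquoted).
#' @param tukey_on Which factor's levels to compare: `"a"` or `"b"`.
#' @return A `comparison_family` (test `"two_way_tukey"`) whose `omnibus`
#'   tibble has one row per term (`factor_a`, `factor_b`, interaction,
#'   residuals).
#' @export
two_way_anova_tukey <- function(data, value, factor_a, factor_b,
                                tukey_on = c("a", "b")) {
  tukey_on <- match.arg(tukey_on)
  value <- rlang::enquo(value)
  factor_a <- rlang::enquo(factor_a); factor_b <- rlang::enquo(factor_b)
  y <- dplyr::pull(data, !!value)
  A <- factor(dplyr::pull(data, !!factor_a))
  B <- factor(dplyr::pull(data, !!factor_b))
  name_a <- rlang::as_name(factor_a); name_b <- rlang::as_name(factor_b)
  tab <- table(A, B)
  if (any(tab == 0)) {
    empty <- which(tab == 0, arr.ind = TRUE)[1, ]
    abort(sprintf("Empty design cell: %s = '%s', %s = '%s'.",
                  name_a, levels(A)[empty[1]], name_b, levels(B)[empty[2]]))
  }
  if (length(unique(as.vector(tab))) > 1L) {
    warn("Unbalanced two-way design: using type II sums of squares.")
  }
  rss <- function(form) sum(resid(lm(form))^2)
  rss_full <- rss(y ~ A * B); rss_ab <- rss(y ~ A + B)
  rss_a <- rss(y ~ A); rss_b <- rss(y ~ B)
  a <- nlevels(A); b <- nlevels(B); N <- length(y)
  df_res <- N - a * b
  if (df_res < 1L) abort("Interaction requires replicates: no residual degrees of freedom.")
  ss <- c(rss_b - rss_ab, rss_a - rss_ab, rss_ab - rss_full, rss_full)
  dfs <- c(a - 1, b - 1, (a - 1) * (b - 1), df_res)
  mse <- rss_full / df_res
  fstat <- c((ss[1:3] / dfs[1:3]) / mse, NA_real_)
  pval <- c(stats::pf(fstat[1:3], dfs[1:3], df_res, lower.tail = FALSE), NA_real_)
  omnibus <- tibble::tibble(
    term = c(name_a, name_b, paste0(name_a, ":", name_b), "Residuals"),
    df = dfs, sumsq = ss, meansq = ss / dfs,
    statistic = fstat, p.value = pval
  )
  fac <- if (tukey_on == "a") A else B
  k <- nlevels(fac)
  means <- tapply(y, fac, mean)
  ns <- tapply(y, fac, length)
  pairs <- utils::combn(levels(fac), 2L)
  comparisons <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    l1 <- pairs[1, j]; l2 <- pairs[2, j]
    est <- means[[l2]] - means[[l1]]
    se <- sqrt(mse * (1 / ns[[l1]] + 1 / ns[[l2]]))
    tstat <- if (se > 0) est / se else if (est == 0) 0 else Inf * sign(est)
    q <- sqrt(2) * abs(tstat)
    padj <- if (!is.finite(q)) 0 else
      ptukey(q, nmeans = k, df = df_res, lower.tail = FALSE)
    punadj <- if (is.finite(tstat)) 2 * pt(-abs(tstat), df_res) else
      if (tstat == 0) 1 else 0
    tibble::tibble(comparison = paste(l2, "-", l1), estimate = est,
                   std.error = se, statistic = tstat, df = df_res,
                   p.value = punadj, adj.p.value = max(padj, punadj))
  })
  new_comparison_family("two_way_tukey", comparisons, omnibus, df_res, mse)
}

#' Map p-values to figure-legend significance stars
#'
#' Strict-inequality tiers matching the usual legend convention: `p < 0.05`
#' one star up to `p < 0.0001` four stars; boundary values take the weaker
#' tier (`p = 0.05` is `"ns"`).
#'
#' @param p Numeric vector of (adjusted) p-values.
#' @return Character vector of `"ns"`, `"*"`, `"**"`, `"***"`, `"****"`.
#' @export
significance_tiers <- function(p) {
  out <- rep("ns", length(p))
  out[p < 0.05] <- "*"
  out[p < 0.01] <- "**"
  out[p < 0.001] <- "***"
  out[p < 0.0001] <- "****"
  out[is.na(p)] <- NA_character_
  out
}
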