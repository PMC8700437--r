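# --- windowing and profiles -------------------------------------------------

#' Split a signal into equal non-overlapping windows
#'
#' Chronological windows of `floor(N / n_windows)` samples; any remainder is
#' discarded from the end of the record.
#'
#' @param x an [emg_signal] or numeric vector.
#' @param n_windows number of windows (default 4).
#' @return List of [emg_signal] objects labelled `W1`, `W2`, ...
#' @export
segment_windows <- function(x, n_windows = 4L) {
  fs <- signal_fs(x, default = 1)
  s <- as_samples(x)
  n_windows <- as.integer(n_windows)
  if (n_windows < 1L || length(s) < n_windows)
    stop("signal shorter than the number of windows", call. = FALSE)
  len <- length(s) %/% n_windows
  lapply(seq_len(n_windows), function(w)
    emg_signal(s[((w - 1L) * len + 1L):(w * len)], fs = fs,
               label = sprintf("W%d", w)))
}

.pe_methods <- c("PE", "MPE", "cMPE", "rcMPE", "DPE", "cDPE", "rcDPE")

#' Entropy of a signal by method name
#'
#' Dispatcher over the estimator family.  `scale` is the coarse-graining
#' scale `m` for the multiscale methods and the downsampling factor `tau`
#' for the downsampling methods (the `tau = m` coupling used when methods are
#' compared at a common scale); `PE` ignores it.
#'
#' @param x an [emg_signal] or numeric vector.
#' @param method one of `"PE"`, `"MPE"`, `"cMPE"`, `"rcMPE"`, `"DPE"`,
#'   `"cDPE"`, `"rcDPE"`.
#' @param scale integer scale / downsampling factor.
#' @inheritParams permutation_entropy
#' @return A single entropy value.
#' @export
entropy_estimate <- function(x, method, scale = 1L, d = 3L, normalized = TRUE,
                             tie_policy = "stable", warn_short = TRUE) {
  method <- match.arg(method, .pe_methods)
  f <- switch(method,
    PE    = function(...) permutation_entropy(x, d = d, tau = 1L, ...),
    MPE   = function(...) mpe(x, m = scale, d = d, ...),
    cMPE  = function(...) cmpe(x, m = scale, d = d, ...),
    rcMPE = function(...) rcmpe(x, m = scale, d = d, ...),
    DPE   = function(...) dpe(x, tau = scale, d = d, ...),
    cDPE  = function(...) cdpe(x, tau = scale, d = d, ...),
    rcDPE = function(...) rcdpe(x, tau = scale, d = d, ...))
  f(normalized = normalized, tie_policy = tie_policy, warn_short = warn_short)
}

#' Entropy-versus-scale profile
#'
#' One entropy value per scale for a given method and dimension; the raw
#' material of scale-selection plots (mean entropy as a function of scale).
#'
#' @inheritParams entropy_estimate
#' @param scales integer scale grid, strictly increasing (default `1:100`).
#' @param label value for the `label` column of the output (defaults to the
#'   signal's label).
#' @return data.frame with columns `label`, `method`, `d`, `scale`, `value`.
#' @export
entropy_profile <- function(x, method = "rcDPE", d = 3L, scales = 1:100,
                            normalized = TRUE, tie_policy = "stable",
                            warn_short = FALSE, label = NULL) {
  method <- match.arg(method, .pe_methods)
  scales <- as.integer(scales)
  if (any(diff(scales) <= 0L) || any(scales < 1L))
    stop("'scales' must be strictly increasing positive integers", call. = FALSE)
  if (is.null(label))
    label <- if (inherits(x, "emg_signal") && nzchar(x$label)) x$label else "signal"
  vals <- vapply(scales, function(m)
    entropy_estimate(x, method, scale = m, d = d, normalized = normalized,
                     tie_policy = tie_policy, warn_short = warn_short),
    numeric(1L))
  data.frame(label = label, method = method, d = as.integer(d),
             scale = scales, value = vals)
}

# --- window deltas and scale selection --------------------------------------

# default pairwise fatigue-step comparisons
.default_pairs <- list(c(1L, 2L), c(1L, 3L), c(1L, 4L), c(2L, 3L), c(3L, 4L))

#' Pairwise window entropy differences
#'
#' For each configured window pair, the earlier-window entropy minus the
#' later-window entropy, at every scale — positive deltas mean complexity
#' loss with fatigue progression.
#'
#' @param profiles data.frame with columns `window` (integer), `scale`,
#'   `value` and any identifying columns (`subject`, `method`, `d`, ...).
#' @param pairs list of integer pairs `c(earlier, later)`; default
#'   `W1-W2, W1-W3, W1-W4, W2-W3, W3-W4`.
#' @return data.frame with the identifying columns plus `pair` (e.g.
#'   `"W1-W4"`) and `delta`.
#' @export
pairwise_deltas <- function(profiles, pairs = NULL) {
  if (is.null(pairs)) pairs <- .default_pairs
  stopifnot(all(c("window", "scale", "value") %in% names(profiles)))
  idcols <- setdiff(names(profiles), c("window", "value"))
  out <- lapply(pairs, function(pr) {
    a <- profiles[profiles$window == pr[1L], , drop = FALSE]
    b <- profiles[profiles$window == pr[2L], , drop = FALSE]
    key <- function(df) do.call(paste, c(df[idcols], sep = "\r"))
    m <- match(key(a), key(b))
    if (anyNA(m))
      stop("profiles are not aligned across windows", call. = FALSE)
    cbind(a[idcols], pair = sprintf("W%d-W%d", pr[1L], pr[2L]),
          delta = a$value - b$value[m])
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Select the most discriminative scale
#'
#' Scale maximizing the mean absolute window delta (averaged over subjects
#' and pairs, and any other grouping present); ties resolve to the smallest
#' scale.
#'
#' @param deltas data.frame from [pairwise_deltas()] with columns `scale` and
#'   `delta`.
#' @return Integer scale.
#' @export
select_scale <- function(deltas) {
  stopifnot(all(c("scale", "delta") %in% names(deltas)))
  crit <- tapply(abs(deltas$delta), deltas$scale, mean)
  scales <- as.integer(names(crit))
  scales[which.max(crit)]   # which.max takes the first (smallest) on ties
}

# --- repeated-measures statistics -------------------------------------------

#' Repeated-measures ANOVA over a fatigue-study table
#'
#' Fits a repeated-measures ANOVA with `stats::aov` and within-subject error
#' strata over the supplied within-subject factors (fatigue step or delta
#' pair, method, embedding dimension), reports Bonferroni-adjusted paired
#' post-hoc comparisons for each significant factor, and screens the
#' normality (Lilliefors) and variance-homogeneity (Levene) assumptions.
#' Screening results are reported, never used to gate the analysis.
#'
#' @param data data.frame with a `subject` column, a `value` column (entropy
#'   or delta), and the factor columns named in `factors`.
#' @param factors character vector of within-subject factor column names
#'   (default the intersection of `c("step", "pair", "method", "d")` with
#'   `names(data)`).
#' @param value name of the response column (default `"value"`).
#' @param alpha significance threshold for post-hoc reporting (default 0.05).
#' @return Object of class `rm_anova_report`: list with `anova`
#'   (data.frame of term, df, F, p), `posthoc` (per factor, Bonferroni-adjusted
#'   paired comparisons), `screening`, `alpha`.
#' @export
run_statistics <- function(data, factors = NULL, value = "value",
                           alpha = 0.05) {
  stopifnot(is.data.frame(data), "subject" %in% names(data),
            value %in% names(data))
  if (is.null(factors))
    factors <- intersect(c("step", "pair", "method", "d"), names(data))
  if (length(factors) < 1L) stop("no factor columns found", call. = FALSE)
  df <- data
  df$subject <- factor(df$subject)
  for (f in factors) df[[f]] <- factor(df[[f]])
  # constant factors carry no contrast; drop them from the model
  factors <- factors[vapply(factors, function(f) nlevels(df[[f]]) > 1L, logical(1L))]
  if (length(factors) < 1L)
    stop("all factor columns are constant; nothing to test", call. = FALSE)
  df$.y <- df[[value]]

  # balanced complete design required by the within-subject error strata
  cells <- table(df[c("subject", factors)])
  if (any(cells != 1L))
    stop("unbalanced design: every subject must contribute exactly one value per factor-level combination",
         call. = FALSE)

  rhs <- paste(factors, collapse = " * ")
  form <- stats::as.formula(sprintf(".y ~ %s + Error(subject/(%s))", rhs, rhs))
  fit <- stats::aov(form, data = df)
  anova_tab <- .tidy_aov_error(fit)

  posthoc <- lapply(stats::setNames(factors, factors), function(f) {
    if (nlevels(df[[f]]) < 2L) return(NULL)
    # paired comparisons: average the response over the other factors first
    agg <- stats::aggregate(df$.y, by = list(subject = df$subject, lev = df[[f]]),
                            FUN = mean)
    pt <- stats::pairwise.t.test(agg$x, agg$lev, paired = TRUE,
                                 p.adjust.method = "bonferroni")
    pt$p.value
  })

  screening <- list(
    lilliefors = tryCatch(suppressWarnings(
      nortest::lillie.test(stats::residuals(stats::lm(df$.y ~ interaction(df[factors]))))$p.value),
      error = function(e) NA_real_),
    levene = tryCatch(suppressWarnings(
      car::leveneTest(df$.y, interaction(df[factors]))[1L, "Pr(>F)"]),
      error = function(e) NA_real_))

  structure(list(anova = anova_tab, posthoc = posthoc,
                 screening = screening, alpha = alpha,
                 factors = factors, n_subjects = nlevels(df$subject)),
            class = "rm_anova_report")
}

# flatten summary.aovlist into term / df1 / df2 / F / p rows
.tidy_aov_error <- function(fit) {
  out <- list()
  for (stratum in summary(fit)) {
    tab <- if (is.list(stratum)) stratum[[1L]] else stratum
    tab <- as.data.frame(tab)
    terms <- trimws(rownames(tab))
    resid_row <- terms == "Residuals"
    if (!any(resid_row)) next
    df2 <- tab$Df[resid_row]
    for (i in which(!resid_row)) {
      out[[length(out) + 1L]] <- data.frame(
        term = terms[i], df1 = tab$Df[i], df2 = df2,
        F = tab$`F value`[i], p = tab$`Pr(>F)`[i])
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' @export
print.rm_anova_report <- function(x, ...) {
  cat(sprintf("<rm_anova_report> %d subjects, factors: %s (alpha = %g)\n",
              x$n_subjects, paste(x$factors, collapse = ", "), x$alpha))
  tab <- x$anova
  for (i in seq_len(nrow(tab)))
    cat(sprintf("  %-20s F(%d,%d) = %8.3f  p = %.4g%s\n", tab$term[i],
                tab$df1[i], tab$df2[i], tab$F[i], tab$p[i],
                if (is.finite(tab$p[i]) && tab$p[i] < x$alpha) "  *" else ""))
  cat(sprintf("  screening: Lilliefors p = %.3g, Levene p = %.3g (reported only)\n",
              x$screening$lilliefors, x$screening$levene))
  invisible(x)
}

# --- full study -------------------------------------------------------------

#' Windowed fatigue-discrimination study
#'
#' Runs the full analysis chain on a cohort: each subject's record is split
#' into `n_windows` equal chronological windows; entropy-versus-scale
#' profiles are computed per window for the scanned methods at the scan
#' dimension; pairwise window deltas are formed and the most discriminative
#' scale selected; finally all methods and dimensions are evaluated at that
#' scale and compared with a repeated-measures ANOVA (factors: fatigue step
#' or delta pair, method, dimension) with Bonferroni post-hoc tests.
#'
#' @param cohort a `fatigue_cohort` from [gen_fatigue_cohort()], or a list of
#'   [emg_signal] records.
#' @param methods methods entered in the final comparison
#'   (default `c("MPE", "rcMPE", "rcDPE")`).
#' @param dims embedding dimensions for the final comparison (default `3:5`).
#' @param scales scale grid scanned for the profiles (default `1:100`).
#' @param scan_method,scan_d method(s) and single dimension used for the
#'   scale scan (defaults: all of `methods`, at `d = 4`).
#' @param n_windows number of fatigue windows (default 4).
#' @param normalized,tie_policy passed to the estimators.
#' @param anova_on `"deltas"` (default) enters the five pairwise window
#'   deltas as the repeated measure; `"windows"` enters the raw per-window
#'   entropies.
#' @return Object of class `fatigue_study`: list with `profiles`, `deltas`,
#'   `selected_scale`, `at_scale` (entropy table at the selected scale for
#'   all methods and dimensions), `anova` (an `rm_anova_report`), `config`.
#' @examples
#' \donttest{
#' co <- gen_fatigue_cohort(cohort_spec(n_subjects = 3, duration_s = 4, fs = 2000,
#'                                      band_end_by_window = c(500, 400, 320, 250)))
#' st <- fatigue_study(co, scales = 1:20, dims = 3:4)
#' st$selected_scale
#' }
#' @export
fatigue_study <- function(cohort, methods = c("MPE", "rcMPE", "rcDPE"),
                          dims = 3:5, scales = 1:100,
                          scan_method = methods, scan_d = 4L,
                          n_windows = 4L, normalized = TRUE,
                          tie_policy = "stable",
                          anova_on = c("deltas", "windows")) {
  anova_on <- match.arg(anova_on)
  methods <- vapply(methods, match.arg, character(1L), choices = .pe_methods)
  scan_method <- vapply(scan_method, match.arg, character(1L), choices = .pe_methods)
  subjects <- if (inherits(cohort, "fatigue_cohort")) cohort$subjects
              else lapply(seq_along(cohort), function(i)
                list(id = sprintf("S%02d", i), signal = cohort[[i]]))

  # 1. scale scan: per-window profiles at the scan dimension
  profiles <- do.call(rbind, lapply(subjects, function(su) {
    wins <- segment_windows(su$signal, n_windows)
    do.call(rbind, lapply(seq_along(wins), function(w)
      do.call(rbind, lapply(scan_method, function(me) {
        pr <- entropy_profile(wins[[w]], method = me, d = scan_d,
                              scales = scales, normalized = normalized,
                              tie_policy = tie_policy, warn_short = FALSE,
                              label = su$id)
        names(pr)[names(pr) == "label"] <- "subject"
        pr$window <- w
        pr
      }))))
  }))

  # 2. deltas and scale selection (selection uses the scanned profiles)
  deltas <- pairwise_deltas(profiles)
  selected_scale <- select_scale(deltas)

  # 3. all methods x dimensions at the selected scale
  at_scale <- do.call(rbind, lapply(subjects, function(su) {
    wins <- segment_windows(su$signal, n_windows)
    grid <- expand.grid(window = seq_along(wins), method = methods, d = dims,
                        stringsAsFactors = FALSE)
    grid$subject <- su$id
    grid$scale <- selected_scale
    grid$value <- mapply(function(w, me, dd)
      entropy_estimate(wins[[w]], me, scale = selected_scale, d = dd,
                       normalized = normalized, tie_policy = tie_policy,
                       warn_short = FALSE),
      grid$window, grid$method, grid$d)
    grid
  }))

  # 4. repeated-measures comparison
  if (anova_on == "deltas") {
    at_scale_prof <- at_scale
    names(at_scale_prof)[names(at_scale_prof) == "window"] <- "window"
    adf <- pairwise_deltas(at_scale_prof)
    names(adf)[names(adf) == "delta"] <- "value"
    anova <- run_statistics(adf, factors = intersect(c("pair", "method", "d"),
                                                     names(adf)))
  } else {
    wdf <- at_scale
    names(wdf)[names(wdf) == "window"] <- "step"
    anova <- run_statistics(wdf, factors = intersect(c("step", "method", "d"),
                                                     names(wdf)))
  }

  structure(list(profiles = profiles, deltas = deltas,
                 selected_scale = selected_scale, at_scale = at_scale,
                 anova = anova,
                 config = list(methods = methods, dims = dims,
                               scales = scales, scan_method = scan_method,
                               scan_d = scan_d, n_windows = n_windows,
                               normalized = normalized,
                               tie_policy = tie_policy,
                               anova_on = anova_on)),
            class = "fatigue_study")
}

#' @export
print.fatigue_study <- function(x, ...) {
  cat(sprintf("<fatigue_study> %d subjects, %d windows, scales %d..%d\n",
              length(unique(x$profiles$subject)), x$config$n_windows,
              min(x$config$scales), max(x$config$scales)))
  cat(sprintf("  selected scale: %d\n", x$selected_scale))
  mw <- stats::aggregate(value ~ window,
                         data = x$at_scale[x$at_scale$method == x$config$methods[length(x$config$methods)] &
                                           x$at_scale$d == x$config$scan_d, ],
                         FUN = mean)
  cat("  mean entropy by window (last method, scan d): ",
      paste(sprintf("W%d=%.4f", mw$window, mw$value), collapse = "  "), "\n")
  print(x$anova)
  invisible(x)
}
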