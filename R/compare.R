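#' Pair event times between two systems
#'
#' Greedy nearest-neighbour pairing: candidate pairs are considered in
#' order of increasing absolute time difference, each event used at most
#' once, and pairs farther apart than the tolerance are rejected. The
#' default tolerance is half the median inter-event interval, so an event
#' can only match its true counterpart.
#'
#' @param a,b Numeric vectors of event times (seconds), one per system.
#' @param tolerance_s Maximum pairing distance; default half the median
#'   spacing of `a`.
#' @return Data frame with columns `a`, `b`, `diff` (`a - b`); attribute
#'   `"unmatched"` lists the unpaired times per input.
#' @export
match_events <- function(a, b, tolerance_s = NULL) {
  a <- sort(a); b <- sort(b)
  if (is.null(tolerance_s)) {
    gaps <- diff(a)
    tolerance_s <- if (length(gaps)) stats::median(gaps) / 2 else Inf
  }
  if (!length(a) || !length(b)) {
    out <- data.frame(a = numeric(), b = numeric(), diff = numeric())
    attr(out, "unmatched") <- list(a = a, b = b)
    return(out)
  }
  d <- abs(outer(a, b, "-"))
  ord <- order(d)
  used_a <- logical(length(a)); used_b <- logical(length(b))
  pairs <- list()
  for (k in ord) {
    if (d[k] > tolerance_s) break
    i <- (k - 1L) %% length(a) + 1L
    j <- (k - 1L) %/% length(a) + 1L
    if (used_a[i] || used_b[j]) next
    used_a[i] <- TRUE; used_b[j] <- TRUE
    pairs[[length(pairs) + 1L]] <- c(a[i], b[j])
  }
  m <- if (length(pairs)) do.call(rbind, pairs) else matrix(numeric(), 0L, 2L)
  m <- m[order(m[, 1]), , drop = FALSE]
  out <- data.frame(a = m[, 1], b = m[, 2], diff = m[, 1] - m[, 2])
  attr(out, "unmatched") <- list(a = a[!used_a], b = b[!used_b])
  out
}

#' Paired difference statistics
#'
#' Mean and SD of the signed differences `a - b`, mean and SD of the
#' absolute differences, and the raw range of the signed differences —
#' the summary layout used for between-system event-time and
#' gait-parameter tables.
#'
#' @param a,b Paired numeric vectors of equal length.
#' @return Named list: `n`, `mean_diff`, `sd_diff`, `mean_abs`, `sd_abs`,
#'   `min_diff`, `max_diff`.
#' @export
difference_stats <- function(a, b) {
  stopifnot(length(a) == length(b))
  ok <- !is.na(a) & !is.na(b)
  d <- a[ok] - b[ok]
  list(n = length(d),
       mean_diff = mean(d), sd_diff = stats::sd(d),
       mean_abs = mean(abs(d)), sd_abs = stats::sd(abs(d)),
       min_diff = if (length(d)) min(d) else NA_real_,
       max_diff = if (length(d)) max(d) else NA_real_)
}

#' Pearson correlation between two systems
#'
#' @param x,y Paired numeric vectors.
#' @return List with `r` and `p` (two-sided test); `r` is `NA` with a
#'   `zero_variance` flag when either vector is constant.
#' @export
pearson_r <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L || stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, zero_variance = TRUE))
  ct <- stats::cor.test(x, y)
  list(r = unname(ct$estimate), p = ct$p.value, zero_variance = FALSE)
}

# Two-way mean squares for n subjects x k=2 raters, one observation per
# cell: rows (subjects), columns (raters), residual.
.icc_ms <- function(x, y) {
  m <- cbind(x, y)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  n <- nrow(m); k <- ncol(m)
  if (n < 3L) stop("ICC needs at least 3 paired observations")
  grand <- mean(m)
  msr <- k * sum((rowMeans(m) - grand)^2) / (n - 1)
  msc <- n * sum((colMeans(m) - grand)^2) / (k - 1)
  sst <- sum((m - grand)^2)
  mse <- (sst - msr * (n - 1) - msc * (k - 1)) / ((n - 1) * (k - 1))
  list(n = n, k = k, msr = msr, msc = msc, mse = mse)
}

#' Intraclass correlation coefficients for two raters
#'
#' Two-way single-measure intraclass correlations in the McGraw-Wong
#' forms, from the subjects (`MS_R`), raters (`MS_C`) and error (`MS_E`)
#' mean squares of the two-way layout:
#' \itemize{
#'   \item consistency `ICC(C,1) = (MS_R - MS_E) / (MS_R + (k-1) MS_E)` —
#'     insensitive to a systematic offset between systems;
#'   \item absolute agreement
#'     `ICC(A,1) = (MS_R - MS_E) / (MS_R + (k-1) MS_E + (k/n)(MS_C - MS_E))`
#'     — penalizes systematic offset.
#' }
#' The significance test (against zero) uses `F = MS_R / MS_E` with
#' `(n-1, (n-1)(k-1))` degrees of freedom.
#'
#' @param x,y Paired numeric vectors (the two raters/systems), `n >= 3`.
#' @return List with `icc`, `p` and the mean squares used.
#' @export
icc_c1 <- function(x, y) {
  ms <- .icc_ms(x, y)
  icc <- (ms$msr - ms$mse) / (ms$msr + (ms$k - 1) * ms$mse)
  p <- stats::pf(ms$msr / ms$mse, ms$n - 1, (ms$n - 1) * (ms$k - 1),
                 lower.tail = FALSE)
  c(list(icc = icc, p = p), ms)
}

#' @rdname icc_c1
#' @export
icc_a1 <- function(x, y) {
  ms <- .icc_ms(x, y)
  icc <- (ms$msr - ms$mse) /
    (ms$msr + (ms$k - 1) * ms$mse + (ms$k / ms$n) * (ms$msc - ms$mse))
  p <- stats::pf(ms$msr / ms$mse, ms$n - 1, (ms$n - 1) * (ms$k - 1),
                 lower.tail = FALSE)
  c(list(icc = icc, p = p), ms)
}

#' One-way repeated-measures ANOVA with Bonferroni post-hoc tests
#'
#' Classical within-subject one-way ANOVA (no sphericity correction)
#' comparing measurement systems, followed — regardless of the main
#' effect — by paired t-tests for every system pair with Bonferroni
#' correction (p multiplied by the number of comparisons, capped at 1).
#'
#' @param m Numeric matrix, subjects in rows, measurement systems in
#'   columns (named columns label the post-hoc pairs).
#' @return List with `F`, `df`, `p`, and `posthoc`: data frame of pairs
#'   with mean difference and Bonferroni-adjusted p-value.
#' @export
rm_anova_bonferroni <- function(m) {
  m <- as.matrix(m)
  if (is.null(colnames(m)) || any(!nzchar(colnames(m))))
    colnames(m) <- paste0("sys", seq_len(ncol(m)))
  n <- nrow(m); k <- ncol(m)
  stopifnot(n >= 2L, k >= 2L)
  long <- data.frame(value = as.vector(m),
                     system = factor(rep(colnames(m), each = n),
                                     levels = colnames(m)),
                     subject = factor(rep(seq_len(n), k)))
  fit <- stats::aov(value ~ system + Error(subject), data = long)
  tab <- summary(fit)[["Error: Within"]][[1]]
  Fv <- tab["system", "F value"]
  pv <- tab["system", "Pr(>F)"]
  df <- c(tab["system", "Df"], tab["Residuals", "Df"])
  # degenerate layouts (zero between-system or zero residual variation)
  # make the F ratio numerically meaningless; resolve them explicitly
  grand <- mean(m)
  ss_tot <- sum((m - grand)^2)
  ss_sys <- n * sum((colMeans(m) - grand)^2)
  eps <- 1e-12 * max(ss_tot, 1e-300)
  if (ss_sys <= eps) {Fv <- 0; pv <- 1}
  else if (!is.finite(Fv)) {Fv <- Inf; pv <- 0}
  pairs <- utils::combn(colnames(m), 2)
  ph <- apply(pairs, 2, function(pr) {
    d <- m[, pr[1]] - m[, pr[2]]
    p <- if (stats::sd(d) == 0) 1 else stats::t.test(d)$p.value
    data.frame(pair = paste(pr, collapse = " v "),
               mean_diff = mean(d),
               p_adj = min(1, p * ncol(pairs)))
  })
  list(F = unname(Fv), df = unname(df), p = unname(pv),
       posthoc = do.call(rbind, ph))
}

#' Cross-correlation at time lag zero
#'
#' Normalized (Pearson-type) correlation of two equal-length waveforms
#' without any time shift — the similarity measure used for mean
#' joint-angle trajectories across the gait cycle.
#'
#' @param a,b Equal-length numeric vectors.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
xcorr_lag0 <- function(a, b) {
  stopifnot(length(a) == length(b))
  ok <- !is.na(a) & !is.na(b)
  stats::cor(a[ok], b[ok])
}

#' Mean absolute error between angle curves
#'
#' Mean over all cycle samples (and strides, for matrices) of the absolute
#' difference between two systems' angle profiles, in degrees.
#'
#' @param cycles_a,cycles_b Equal-size numeric vectors or matrices.
#' @return Scalar MAE.
#' @export
mae_curves <- function(cycles_a, cycles_b) {
  stopifnot(length(cycles_a) == length(cycles_b))
  mean(abs(cycles_a - cycles_b), na.rm = TRUE)
}

#' Bin gait cycles by walkway position
#'
#' Assigns each record to a walkway region by its mean anterior-posterior
#' trunk position, with the walkway midpoint as origin: `Start` below
#' `-bound`, `Middle` within `[-bound, bound]`, `End` above `bound`
#' (default bound 0.50 m).
#'
#' @param position Numeric vector of positions (m, walkway midpoint = 0).
#' @param bound Half-width of the middle region (default 0.5).
#' @return Factor with levels `Start`, `Middle`, `End`.
#' @export
bin_by_walkway <- function(position, bound = 0.5) {
  cut(position, breaks = c(-Inf, -bound, bound, Inf),
      labels = c("Start", "Middle", "End"), right = TRUE)
}

#' Between-system comparison report
#'
#' Full agreement analysis between two analysis runs of the same walking
#' bout (e.g., motion capture vs a pose-estimation view, or two camera
#' views): paired event-time differences per side and event type;
#' step-wise spatiotemporal parameter differences (steps paired by
#' heel-strike time), with Pearson r and both intraclass correlations
#' when enough steps pair; participant-mean joint-angle MAE and lag-zero
#' cross-correlation per leg and joint; and per-stride angle MAE binned by
#' walkway position.
#'
#' @param run_a,run_b `gait_analysis` objects from [analyze_trajectories()]
#'   (system A and B; differences are reported as A - B).
#' @param tolerance_s Event-pairing tolerance (default: half the median
#'   step time of run A).
#' @param walkway_bound Walkway bin half-width in meters (default 0.5).
#' @param walkway_origin Anterior-posterior position of the walkway
#'   midpoint in run A's coordinates (default 0). Marker data are
#'   usually centered already; pose-derived coordinates have their origin
#'   at an image corner, so pass `s * image_width / 2` for a centered
#'   camera.
#' @return Nested list of class `comparison_report`.
#' @export
compare_runs <- function(run_a, run_b, tolerance_s = NULL,
                         walkway_bound = 0.5, walkway_origin = 0) {
  stopifnot(inherits(run_a, "gait_analysis"), inherits(run_b, "gait_analysis"))
  if (is.null(tolerance_s)) {
    mst <- stats::median(run_a$steps$step_time, na.rm = TRUE)
    tolerance_s <- if (is.finite(mst)) mst / 2 else 0.3
  }
  rep <- list(systems = c(a = run_a$label, b = run_b$label),
              tolerance_s = tolerance_s)

  # -- event times ----------------------------------------------------
  rep$events <- list()
  for (side in c("left", "right")) for (evt in c("heel_strike", "toe_off")) {
    ta <- run_a$events$time_s[run_a$events$side == side &
                                run_a$events$event == evt]
    tb <- run_b$events$time_s[run_b$events$side == side &
                                run_b$events$event == evt]
    mm <- match_events(ta, tb, tolerance_s)
    rep$events[[paste(side, evt, sep = "_")]] <-
      c(difference_stats(mm$a, mm$b),
        list(n_unmatched_a = length(attr(mm, "unmatched")$a),
             n_unmatched_b = length(attr(mm, "unmatched")$b)))
  }

  # -- spatiotemporal parameters (steps paired by heel-strike time) ----
  sa <- as.data.frame(run_a$steps); sb <- as.data.frame(run_b$steps)
  rep$spatiotemporal <- list()
  for (side in c("left", "right")) {
    pa <- sa[sa$side == side, ]; pb <- sb[sb$side == side, ]
    mm <- match_events(pa$hs_time, pb$hs_time, tolerance_s)
    ia <- match(mm$a, pa$hs_time); ib <- match(mm$b, pb$hs_time)
    for (p in c("step_time", "stance_time", "swing_time",
                "double_support_time", "step_length")) {
      va <- pa[[p]][ia]; vb <- pb[[p]][ib]
      ok <- !is.na(va) & !is.na(vb)
      entry <- rep$spatiotemporal[[p]]
      if (is.null(entry)) entry <- list(a = numeric(), b = numeric())
      entry$a <- c(entry$a, va[ok])
      entry$b <- c(entry$b, vb[ok])
      rep$spatiotemporal[[p]] <- entry
    }
  }
  for (p in names(rep$spatiotemporal)) {
    va <- rep$spatiotemporal[[p]]$a; vb <- rep$spatiotemporal[[p]]$b
    res <- difference_stats(va, vb)
    if (length(va) >= 3L && stats::sd(va) > 0 && stats::sd(vb) > 0) {
      res$r <- pearson_r(va, vb)$r
      res$icc_c1 <- icc_c1(va, vb)$icc
      res$icc_a1 <- icc_a1(va, vb)$icc
    }
    rep$spatiotemporal[[p]] <- res
  }
  gs_a <- participant_summary(run_a$steps)$gait_speed
  gs_b <- participant_summary(run_b$steps)$gait_speed
  rep$gait_speed <- list(a = gs_a, b = gs_b, diff = gs_a - gs_b)

  # -- joint angles ----------------------------------------------------
  rep$angles <- list()
  for (leg in c("left", "right")) for (j in c("hip", "knee", "ankle")) {
    ma <- run_a$cycles[[leg]]$mean[[j]]
    mb <- run_b$cycles[[leg]]$mean[[j]]
    if (is.null(ma) || is.null(mb) || all(is.na(ma)) || all(is.na(mb))) next
    rep$angles[[paste(leg, j, sep = "_")]] <-
      list(mae_deg = mae_curves(ma, mb), xcorr_lag0 = xcorr_lag0(ma, mb))
  }

  # -- per-stride angle MAE binned by walkway position -----------------
  rep$walkway_bins <- list()
  for (leg in c("left", "right")) {
    ca <- run_a$cycles[[leg]]; cb <- run_b$cycles[[leg]]
    if (!length(ca$hs_time) || !length(cb$hs_time)) next
    mm <- match_events(ca$hs_time, cb$hs_time, tolerance_s)
    ia <- match(mm$a, ca$hs_time); ib <- match(mm$b, cb$hs_time)
    if (!length(ia)) next
    bins <- bin_by_walkway(ca$walkway[ia] - walkway_origin, walkway_bound)
    for (j in c("hip", "knee", "ankle")) {
      per_stride <- vapply(seq_along(ia), function(s)
        mae_curves(ca[[j]][ia[s], ], cb[[j]][ib[s], ]), numeric(1))
      for (bn in levels(bins)) {
        v <- per_stride[bins == bn]
        if (!length(v)) next
        rep$walkway_bins[[paste(leg, j, bn, sep = "_")]] <-
          list(mae_deg = mean(v), n = length(v))
      }
    }
  }
  class(rep) <- "comparison_report"
  rep
}
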