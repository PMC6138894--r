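#' Inter-observer and computer-observer agreement statistics
#'
#' Pairwise absolute and relative measurement differences and Bland-Altman
#' bias with 1.96-SD limits of agreement, as used to compare automated
#' measurements against human observers and human observers against each
#' other.
#'
#' @name agreement
NULL

#' Paired absolute and relative differences
#'
#' For measurement pairs (a, b): the mean and sample SD (n-1) of `|a - b|`,
#' and of the relative difference `100 * |a - b| / ((a + b) / 2)` percent.
#' Pairs with `a + b = 0` are excluded from the relative statistics and
#' counted in `n_excluded`.
#'
#' @param a,b numeric vectors of paired measurements.
#' @return list with `mean_abs`, `sd_abs`, `mean_rel_pct`, `sd_rel_pct`,
#'   `n`, `n_excluded`.
#' @export
paired_differences <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 1L)
  ad <- abs(a - b)
  denom <- (a + b) / 2
  ok <- denom != 0
  rel <- 100 * ad[ok] / denom[ok]
  list(mean_abs = mean(ad),
       sd_abs = if (length(ad) > 1L) stats::sd(ad) else 0,
       mean_rel_pct = if (any(ok)) mean(rel) else NA_real_,
       sd_rel_pct = if (sum(ok) > 1L) stats::sd(rel) else 0,
       n = length(a), n_excluded = sum(!ok))
}

#' Bland-Altman agreement statistics
#'
#' Bias is the mean of the differences `a - b`; the limits of agreement are
#' the bias plus/minus 1.96 sample standard deviations. The returned `x`
#' (pair means) and `y` (differences) support the conventional plot.
#'
#' @param a,b numeric vectors of paired measurements, `n >= 2`.
#' @return list with `bias`, `loa_low`, `loa_high`, `sd`, `n`, `x`, `y`.
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2L) stop("need >= 2 pairs")
  d <- a - b
  s <- stats::sd(d)
  bias <- mean(d)
  list(bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
       sd = s, n = length(d), x = (a + b) / 2, y = d)
}

#' Simulated observer study
#'
#' Reproduces the agreement-table machinery over a set of cases: each
#' case's reference (manual) segmentation is compared against an automated
#' segmentation, and three simulated observers are compared pairwise
#' (O1 vs O2, O2 vs O3, O3 vs O1). Observers are produced by
#' [simulate_observer()] with the given boundary jitter.
#'
#' @param cases list of `phantom_case` objects (>= 2).
#' @param auto either an `fcn_network` (applied with [segment_stack()]) or a
#'   function `case -> segmentation_map`; defaults to returning the truth.
#' @param jitter_mm length-3 RMS boundary jitter of the observers, mm.
#' @param seed base RNG seed; observer k of case i uses `seed + 10*i + k`.
#' @return list with `metrics` (structure-level Dice/MCD/HD per case and
#'   comparison) and `measures` (per-measure paired difference and
#'   Bland-Altman summaries per comparison), both data frames.
#' @export
observer_study <- function(cases, auto = NULL,
                           jitter_mm = c(1.8, 1.8, 1.8), seed = 1L) {
  if (length(cases) < 2L) stop("need at least 2 cases")
  auto_fun <- if (is.null(auto)) function(case) case$truth
    else if (inherits(auto, "fcn_network")) {
      function(case) segment_stack(auto, case$stack, scheme = case$truth$scheme)
    } else auto
  comparisons <- c("Auto vs Manual", "O1 vs O2", "O2 vs O3", "O3 vs O1")
  met_rows <- list()
  meas <- list()
  for (i in seq_along(cases)) {
    case <- cases[[i]]
    truth <- case$truth
    obs <- lapply(1:3, function(k) {
      simulate_observer(truth, jitter_mm[k], seed = seed + 10L * i + k)
    })
    segs <- list(`Auto vs Manual` = list(auto_fun(case), truth),
                 `O1 vs O2` = list(obs[[1]], obs[[2]]),
                 `O2 vs O3` = list(obs[[2]], obs[[3]]),
                 `O3 vs O1` = list(obs[[3]], obs[[1]]))
    for (cmp in comparisons) {
      m <- evaluate_case(segs[[cmp]][[1]], segs[[cmp]][[2]])
      m$comparison <- cmp
      m$case <- i
      met_rows[[length(met_rows) + 1L]] <- m
      r1 <- as.data.frame(measures_report(segs[[cmp]][[1]]))
      r2 <- as.data.frame(measures_report(segs[[cmp]][[2]]))
      meas[[length(meas) + 1L]] <-
        cbind(comparison = cmp, case = i, side = c("a", "b"), rbind(r1, r2))
    }
  }
  metrics <- do.call(rbind, met_rows)
  meas <- do.call(rbind, meas)
  measure_cols <- setdiff(names(meas), c("comparison", "case", "side"))
  summaries <- list()
  for (cmp in comparisons) {
    sub <- meas[meas$comparison == cmp, ]
    a <- sub[sub$side == "a", ]; b <- sub[sub$side == "b", ]
    for (mc in measure_cols) {
      av <- a[[mc]]; bv <- b[[mc]]
      if (all(is.na(av)) || all(is.na(bv))) next
      pd <- paired_differences(av, bv)
      ba <- if (length(av) >= 2L) bland_altman(av, bv) else NULL
      summaries[[length(summaries) + 1L]] <- data.frame(
        comparison = cmp, measure = mc,
        mean_abs = pd$mean_abs, sd_abs = pd$sd_abs,
        mean_rel_pct = pd$mean_rel_pct, sd_rel_pct = pd$sd_rel_pct,
        bias = if (is.null(ba)) NA_real_ else ba$bias,
        loa_low = if (is.null(ba)) NA_real_ else ba$loa_low,
        loa_high = if (is.null(ba)) NA_real_ else ba$loa_high,
        n = pd$n, stringsAsFactors = FALSE)
    }
  }
  list(metrics = metrics, measures = do.call(rbind, summaries))
}
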