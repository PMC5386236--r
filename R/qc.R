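#' Quality control of chamber closures
#'
#' Implements the three-stage cleaning used for automated chamber records:
#'
#' 1. **Dead band**: the first `dead_band` records of each closure (the
#'    20-30 s after lid closure before chamber air reaches the analyser)
#'    are discarded.
#' 2. **Iterative outlier rejection**: CO2 is regressed against closure
#'    time by ordinary least squares; records whose absolute residual
#'    exceeds `m` times the residual standard deviation are removed and the
#'    regression repeated, for `passes` total fits (default 3: the initial
#'    fit plus two repeats), stopping early when no record is removed.
#' 3. **Usability**: a closure is usable when the final fit's Pearson
#'    correlation satisfies `|r| >= r_threshold` (default 0.95) and at
#'    least `min_points` records remain.  Closures whose fitted slope is
#'    statistically indistinguishable from zero (95% CI includes 0) *and*
#'    whose residual scatter is below `zero_noise_max` ppm are marked
#'    `usable_zero` and kept: near-zero winter fluxes make `r` meaningless
#'    and must not be discarded wholesale.
#'
#' The residual standard deviation uses denominator `n - 1` (the sd of the
#' residuals).  With zero residual scatter no record is removed (no
#' division is performed).
#'
#' @param segments Segmented record tibble from [segment_closures()].
#' @param dead_band Number of initial records per closure to discard.
#' @param passes Total number of regression fits (initial + repeats).
#' @param m Outlier criterion in residual standard deviations.
#' @param r_threshold Usability threshold on `|r|`.
#' @param min_points Minimum retained records for a usable closure.
#' @param zero_noise_max Residual-sd bound (ppm) for the `usable_zero`
#'   rule; `NULL` disables it.
#'
#' @return An object of class `closure_qc`: a list with
#'   * `closures`: one row per closure — `closure`, `chamber`, `treatment`,
#'     `vs_ratio`, `time` (closure start), `slope` (ppm s-1), `intercept`,
#'     `r`, `resid_sd`, `se_slope`, `n_records`, `n_used`, `n_dead_band`,
#'     `n_outliers`, `usable`, `flags` (semicolon-joined tokens);
#'   * `records`: the input records with `qc_keep` and `qc_reason`
#'     (`dead_band`, `outlier_pass<k>`, `short_segment`, or `NA` if kept).
#' @examples
#' camp <- simulate_campaign("2009-07-01", "2009-07-02",
#'   instrument = instrument_model(n_chambers = 3), seed = 2)
#' seg <- segment_closures(camp$raw, camp$meta)
#' qc <- qc_closures(seg)
#' head(qc$closures)
#' @export
qc_closures <- function(segments, dead_band = 3, passes = 3, m = 3,
                        r_threshold = 0.95, min_points = 10,
                        zero_noise_max = 1) {
  stopifnot(dead_band >= 0, passes >= 1, m > 0)
  df <- segments[!is.na(segments$closure), , drop = FALSE]
  g <- df$closure
  ## compact group index
  gi <- match(g, sort(unique(g)))
  G <- max(gi)
  t <- df$offset_s
  y <- df$co2_ppm
  ## segments are contiguous runs of their group index
  ord_in_seg <- sequence(rle(gi)$lengths)

  reason <- rep(NA_character_, nrow(df))
  keep <- rep(TRUE, nrow(df))
  keep[df$short] <- FALSE
  reason[df$short] <- "short_segment"
  db <- keep & ord_in_seg <= dead_band
  keep[db] <- FALSE
  reason[db] <- "dead_band"

  for (p in seq_len(passes)) {
    fit <- ols_by_group(t, y, gi, keep, G)
    if (p == passes) break
    res_sd <- fit$resid_sd[gi]
    e <- y - fit$intercept[gi] - fit$slope[gi] * t
    out <- keep & !is.na(res_sd) & res_sd > 0 & abs(e) > m * res_sd
    if (!any(out)) break
    keep[out] <- FALSE
    reason[out] <- paste0("outlier_pass", p)
  }
  fit <- ols_by_group(t, y, gi, keep, G)

  first_idx <- which(!duplicated(gi))
  first_idx <- first_idx[order(gi[first_idx])]
  kept_mean <- function(x) {
    w <- keep & is.finite(x)
    s <- group_sum(ifelse(w, x, 0), gi, G)
    n <- group_sum(as.numeric(w), gi, G)
    ifelse(n > 0, s / n, NA_real_)
  }
  info <- tibble::tibble(
    closure = df$closure[first_idx],
    chamber = df$chamber[first_idx],
    treatment = df$treatment[first_idx],
    vs_ratio = df$vs_ratio[first_idx],
    time = df$timestamp[first_idx],
    p_air = kept_mean(df$p_air_kpa),
    p_cell = kept_mean(df$p_cell_kpa),
    t_air = kept_mean(df$t_air_c),
    t_soil = kept_mean(df$t_soil_c),
    n_records = tabulate(gi, G),
    n_used = as.integer(group_sum(as.numeric(keep), gi, G)),
    n_dead_band = as.integer(group_sum(
      as.numeric(!is.na(reason) & reason == "dead_band"), gi, G)),
    n_outliers = as.integer(group_sum(
      as.numeric(!is.na(reason) & grepl("^outlier", reason)), gi, G)),
    short = group_sum(as.numeric(df$short), gi, G) > 0
  )

  cl <- dplyr::bind_cols(info, tibble::as_tibble(fit)) %>%
    flag_usability(r_threshold = r_threshold, min_points = min_points,
                   zero_noise_max = zero_noise_max)

  records <- df
  records$qc_keep <- keep
  records$qc_reason <- reason

  structure(list(closures = cl, records = records,
                 params = list(dead_band = dead_band, passes = passes,
                               m = m, r_threshold = r_threshold,
                               min_points = min_points,
                               zero_noise_max = zero_noise_max)),
            class = "closure_qc")
}

#' @export
print.closure_qc <- function(x, ...) {
  cat("<closure_qc>\n")
  cat(sprintf("  %s closures, %s usable (%.1f%%)\n",
              format(nrow(x$closures), big.mark = ","),
              format(sum(x$closures$usable), big.mark = ","),
              100 * mean(x$closures$usable)))
  cat(sprintf("  records: %s kept / %s total; %s dead band, %s outliers\n",
              format(sum(x$records$qc_keep), big.mark = ","),
              format(nrow(x$records), big.mark = ","),
              format(sum(x$closures$n_dead_band), big.mark = ","),
              format(sum(x$closures$n_outliers), big.mark = ",")))
  invisible(x)
}

## Sum x within groups gi, returning a dense length-G vector.
group_sum <- function(x, gi, G) {
  out <- numeric(G)
  a <- rowsum(x, gi, reorder = TRUE)
  out[as.integer(rownames(a))] <- a
  out
}

## Grouped OLS of y on t over rows with w TRUE.  Returns per-group vectors.
## Residual sd uses denominator (n - 1); r is the signed Pearson correlation.
ols_by_group <- function(t, y, gi, w, G) {
  wn <- as.numeric(w)
  agg <- rowsum(cbind(n = wn, st = t * wn, sy = y * wn, stt = t * t * wn,
                      sty = t * y * wn, syy = y * y * wn),
                gi, reorder = TRUE)
  full <- matrix(0, nrow = G, ncol = 6,
                 dimnames = list(NULL, colnames(agg)))
  full[as.integer(rownames(agg)), ] <- agg
  n <- full[, "n"]
  sxx <- full[, "stt"] - full[, "st"]^2 / pmax(n, 1)
  syy <- full[, "syy"] - full[, "sy"]^2 / pmax(n, 1)
  sxy <- full[, "sty"] - full[, "st"] * full[, "sy"] / pmax(n, 1)
  slope <- ifelse(n >= 2 & sxx > 0, sxy / sxx, NA_real_)
  intercept <- ifelse(n >= 1, full[, "sy"] / pmax(n, 1), NA_real_) -
    ifelse(is.na(slope), 0, slope) * full[, "st"] / pmax(n, 1)
  r <- ifelse(n >= 2 & sxx > 0 & syy > 0, sxy / sqrt(sxx * syy), NA_real_)
  rss <- pmax(0, syy - ifelse(is.na(slope), 0, slope) * sxy)
  resid_sd <- ifelse(n >= 2, sqrt(rss / pmax(n - 1, 1)), NA_real_)
  se_slope <- ifelse(n >= 3 & sxx > 0,
                     sqrt(rss / pmax(n - 2, 1) / sxx), NA_real_)
  lapply(list(slope = slope, intercept = intercept, r = r,
              resid_sd = resid_sd, se_slope = se_slope), unname)
}

## Usability flags for a closure summary table.
flag_usability <- function(cl, r_threshold, min_points, zero_noise_max) {
  tcrit <- qt(0.975, pmax(cl$n_used - 2, 1))
  zero_ok <- if (is.null(zero_noise_max)) {
    rep(FALSE, nrow(cl))
  } else {
    !is.na(cl$se_slope) &
      (is.na(cl$slope) | abs(cl$slope) <= tcrit * cl$se_slope) &
      !is.na(cl$resid_sd) & cl$resid_sd <= zero_noise_max
  }
  ## a flat, noise-free trace has undefined r but zero slope: usable-zero
  zero_ok <- zero_ok | (!is.na(cl$resid_sd) & cl$resid_sd == 0 &
                          is.na(cl$r) & cl$n_used >= min_points &
                          !is.null(zero_noise_max))
  low_r <- is.na(cl$r) | abs(cl$r) < r_threshold
  too_few <- cl$n_used < min_points
  cl$usable <- (!low_r | zero_ok) & !too_few & !cl$short
  flags <- cbind(
    ifelse(cl$short, "short", NA),
    ifelse(too_few, "too_few_points", NA),
    ifelse(low_r & !zero_ok, "low_r", NA),
    ifelse(zero_ok & low_r, "usable_zero", NA),
    ifelse(cl$n_outliers > 0, "outliers_removed", NA)
  )
  cl$flags <- apply(flags, 1, function(x) paste(stats::na.omit(x),
                                                collapse = ";"))
  cl
}

#' Strip the dead band from a single closure segment
#'
#' Removes the first `k` records of one closure segment (the dead band
#' after lid closure) and labels them; remaining record offsets are
#' preserved.  A segment entirely consumed by the dead band is flagged
#' unusable.
#'
#' @param segment Tibble of one closure's records with columns `offset_s`
#'   and `co2_ppm`.
#' @param k Number of records to strip (>= 0).
#' @return The segment with columns `qc_keep` and `qc_reason` set for the
#'   dead-band records, and attribute `usable` (`FALSE` when nothing
#'   remains).
#' @examples
#' seg <- tibble::tibble(offset_s = seq(0, 230, 10), co2_ppm = 400 + 0.1 * seq(0, 230, 10))
#' sum(strip_dead_band(seg, 3)$qc_keep)
#' @export
strip_dead_band <- function(segment, k = 3) {
  stopifnot(k >= 0)
  segment$qc_keep <- seq_len(nrow(segment)) > k
  segment$qc_reason <- ifelse(segment$qc_keep, NA_character_, "dead_band")
  attr(segment, "usable") <- any(segment$qc_keep)
  segment
}

#' Iterative regression-based outlier rejection for one segment
#'
#' Repeatedly fits CO2 against closure time by OLS and removes records
#' whose absolute residual exceeds `m` times the residual standard
#' deviation, for `passes` total fits, stopping early when nothing is
#' removed.  Records already flagged (e.g. dead band via
#' [strip_dead_band()]) are ignored by the fits.
#'
#' @param segment One closure's records (`offset_s`, `co2_ppm`, optionally
#'   `qc_keep`/`qc_reason` from a prior stage).
#' @param passes Total number of fits (default 3).
#' @param m Rejection criterion in residual standard deviations.
#' @param min_points Minimum retained records for the result to be usable.
#' @return A list of class `qc_result`: `retained` (indices), `rejected`
#'   (tibble of index + reason), `fit` (slope, intercept, r, resid_sd,
#'   se_slope, n), and `n_passes_run`.
#' @export
reject_outliers <- function(segment, passes = 3, m = 3, min_points = 10) {
  stopifnot(passes >= 1, m > 0, nrow(segment) >= 3)
  keep <- if ("qc_keep" %in% names(segment)) segment$qc_keep
          else rep(TRUE, nrow(segment))
  reason <- if ("qc_reason" %in% names(segment)) segment$qc_reason
            else rep(NA_character_, nrow(segment))
  t <- segment$offset_s
  y <- segment$co2_ppm
  gi <- rep(1L, length(t))
  p_run <- 0L
  for (p in seq_len(passes)) {
    fit <- ols_by_group(t, y, gi, keep, 1L)
    p_run <- p
    if (p == passes) break
    if (is.na(fit$resid_sd) || fit$resid_sd == 0) break
    e <- y - fit$intercept - fit$slope * t
    out <- keep & abs(e) > m * fit$resid_sd
    if (!any(out)) break
    keep[out] <- FALSE
    reason[out] <- paste0("outlier_pass", p)
  }
  fit <- ols_by_group(t, y, gi, keep, 1L)
  structure(
    list(retained = which(keep),
         rejected = tibble::tibble(index = which(!keep),
                                   reason = reason[!keep]),
         fit = list(slope = fit$slope, intercept = fit$intercept, r = fit$r,
                    resid_sd = fit$resid_sd, se_slope = fit$se_slope,
                    n = sum(keep)),
         n_passes_run = p_run,
         min_points = min_points),
    class = "qc_result"
  )
}

#' Usability of a single QC result
#'
#' A closure is usable when the final fit has `|r| >= r_threshold` and at
#' least `min_points` retained records; see [qc_closures()] for the
#' near-zero-flux provision.
#'
#' @param qc A `qc_result` from [reject_outliers()].
#' @param r_threshold Threshold on `|r|`.
#' @param min_points Minimum retained records.
#' @param zero_noise_max Residual-sd bound for the usable-zero rule;
#'   `NULL` disables it.
#' @return Logical scalar with attribute `"flags"`.
#' @export
usability <- function(qc, r_threshold = 0.95, min_points = 10,
                      zero_noise_max = 1) {
  f <- qc$fit
  cl <- tibble::tibble(slope = f$slope, r = f$r, resid_sd = f$resid_sd,
                       se_slope = f$se_slope, n_used = f$n,
                       n_outliers = nrow(qc$rejected), short = FALSE)
  cl <- flag_usability(cl, r_threshold, min_points, zero_noise_max)
  structure(cl$usable, flags = cl$flags)
}
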