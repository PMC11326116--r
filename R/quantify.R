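#' Normalize plate traces by the post-day-1 maximum
#'
#' Every reading is divided by the maximum reading of its measurement type
#' (channel) taken at or after the day-1 cutoff, across all wells of the
#' experiment. Readings before the cutoff may therefore exceed 1 if the
#' global maximum fell during day 1.
#'
#' @param traces Data frame with columns `well`, `t_h`, `channel`, `value`
#'   (and optionally `culture_type`).
#' @param day1_cutoff_h Cutoff in hours (default 24).
#' @param scope `"per_channel"` (default: one maximum per channel across all
#'   wells) or `"per_well"`.
#' @return The input data frame with `value` normalized.
#' @export
normalize_after_day1 <- function(traces, day1_cutoff_h = 24,
                                 scope = c("per_channel", "per_well")) {
  scope <- match.arg(scope)
  stopifnot(all(c("t_h", "channel", "value") %in% names(traces)))
  if (any(!is.finite(traces$value))) abort_idc("non-finite readings", "bad_trace")
  key <- if (scope == "per_channel") traces$channel
         else paste(traces$channel, traces$well)
  for (k in unique(key)) {
    sel <- key == k
    post <- traces$value[sel & traces$t_h >= day1_cutoff_h]
    if (length(post) == 0 || max(post) <= 0) {
      abort_idc(sprintf("no positive post-cutoff readings for '%s'", k),
                "bad_trace")
    }
    traces$value[sel] <- traces$value[sel] / max(post)
  }
  traces
}

#' Donor-to-recipient ratio of max-normalized counts
#'
#' Each species' counts are divided by that species' maximum across the
#' experiment, then the ratio normalized-donor / normalized-recipient is
#' taken pairwise. A zero recipient yields a flagged missing value, not
#' infinity.
#'
#' @param donor,recipient Paired count vectors (same length, matched by
#'   day/well).
#' @return Data frame with `norm_donor`, `norm_recipient`, `ratio`, and
#'   logical `flag_zero_recipient`.
#' @export
donor_recipient_ratio <- function(donor, recipient) {
  if (length(donor) != length(recipient)) {
    abort_idc("donor and recipient vectors must be paired", "bad_counts")
  }
  if (any(c(donor, recipient) < 0, na.rm = TRUE)) {
    abort_idc("counts must be >= 0", "bad_counts")
  }
  nd <- donor / max(donor)
  nr <- recipient / max(recipient)
  zero <- nr == 0
  data.frame(norm_donor = nd, norm_recipient = nr,
             ratio = ifelse(zero, NA_real_, nd / nr),
             flag_zero_recipient = zero)
}

#' Log-log regression of IDC counts on donor-to-recipient ratio
#'
#' Gaussian-family, identity-link GLM of `log10(idc)` on `log10(dr)` —
#' i.e. an ordinary linear fit on the log-log scale. Points at the CFU
#' detection limits (counts at or below the 0.1 floor, at or above the 500
#' lawn cap) and non-positive ratios are excluded and counted.
#'
#' @param dr Donor-to-recipient ratios.
#' @param idc Paired IDC CFU counts.
#' @param floor,cap Detection limits (defaults 0.1 and 500).
#' @return List with `slope`, `intercept`, their standard errors `se`,
#'   p-values `p`, 95% confidence intervals `ci`, `n_used`, `n_excluded`,
#'   and the fitted `model`.
#' @export
fit_loglog_glm <- function(dr, idc, floor = 0.1, cap = 500) {
  if (length(dr) != length(idc)) abort_idc("dr and idc must be paired", "bad_counts")
  usable <- is.finite(dr) & is.finite(idc) & dr > 0 & idc > floor & idc < cap
  n_excluded <- sum(!usable)
  if (sum(usable) < 3) {
    abort_idc("fewer than 3 usable points after detection-limit exclusion",
              "underpowered")
  }
  d <- data.frame(x = log10(dr[usable]), y = log10(idc[usable]))
  fit <- stats::glm(y ~ x, family = stats::gaussian(), data = d)
  sm <- summary(fit)$coefficients
  ci <- stats::confint.default(fit)
  list(slope = unname(sm["x", "Estimate"]),
       intercept = unname(sm["(Intercept)", "Estimate"]),
       se = c(intercept = unname(sm["(Intercept)", "Std. Error"]),
              slope = unname(sm["x", "Std. Error"])),
       p = c(intercept = unname(sm["(Intercept)", 4]),
             slope = unname(sm["x", 4])),
       ci = ci, n_used = sum(usable), n_excluded = n_excluded, model = fit)
}

#' Per-day slopes of the log-log D:R vs IDC relationship
#'
#' One [fit_loglog_glm()] per day; days with too few usable points are
#' flagged and skipped rather than failing the table.
#'
#' @param data Data frame with columns `day`, `dr`, `idc`.
#' @param ... Passed to [fit_loglog_glm()].
#' @return Data frame `(day, slope, se, n_used, flag)` sorted by day.
#' @export
daily_slopes <- function(data, ...) {
  stopifnot(all(c("day", "dr", "idc") %in% names(data)))
  days <- sort(unique(data$day))
  rows <- lapply(days, function(d) {
    sub <- data[data$day == d, ]
    fit <- tryCatch(fit_loglog_glm(sub$dr, sub$idc, ...),
                    idcsim_underpowered = function(e) NULL)
    if (is.null(fit)) {
      data.frame(day = d, slope = NA_real_, se = NA_real_, n_used = 0L,
                 flag = "underpowered")
    } else {
      data.frame(day = d, slope = fit$slope, se = unname(fit$se["slope"]),
                 n_used = fit$n_used, flag = "")
    }
  })
  do.call(rbind, rows)
}

#' Signed fold decrease of coculture relative to monoculture
#'
#' Computed exactly as reported alongside the CRISPR-killing assays:
#' `-(normalized monoculture signal) / (normalized coculture signal)`. The
#' sign convention is preserved verbatim, so values are negative; a
#' coculture signal of zero gives a flagged missing value.
#'
#' @param norm_mono,norm_co Normalized monoculture and coculture readings
#'   (vectors recycle as usual).
#' @return Numeric vector; `NA` where `norm_co == 0` (with a
#'   `flag_zero_coculture` attribute marking those positions).
#' @export
fold_decrease <- function(norm_mono, norm_co) {
  zero <- norm_co == 0
  out <- ifelse(zero, NA_real_, -norm_mono / norm_co)
  attr(out, "flag_zero_coculture") <- zero
  out
}

#' Apply CFU counting conventions to raw plate counts
#'
#' Counts of 0 keep the value 0 and get a `detection_floor` flag (the value
#' 0.1 is substituted only for log-scale output, via `log_display`); counts
#' at or above 200 are flagged as estimates; lawns (entered as `Inf`, `NA`
#' with `lawn = TRUE`, or any count >= 500) are recorded as 500 with a
#' `lawn` flag.
#'
#' @param counts Non-negative integer counts; `Inf` marks a lawn.
#' @param dilution Optional per-sample dilution factors (default 1); the
#'   estimated CFU is `value * dilution`.
#' @return Data frame with `raw`, `value`, `dilution`, `estimated_cfu`,
#'   `log_display`, and logical flag columns `flag_floor`, `flag_estimate`,
#'   `flag_lawn`.
#' @export
adjust_cfu <- function(counts, dilution = 1) {
  if (any(counts < 0, na.rm = TRUE)) abort_idc("negative CFU count", "bad_counts")
  dilution <- rep_len(dilution, length(counts))
  lawn <- is.infinite(counts) | counts >= 500
  value <- ifelse(lawn, 500, counts)
  floor_flag <- value == 0
  est <- ifelse(value >= 200 & !lawn, TRUE, FALSE)
  data.frame(
    raw = counts, value = value, dilution = dilution,
    estimated_cfu = value * dilution,
    log_display = ifelse(floor_flag, 0.1, value * dilution),
    flag_floor = floor_flag, flag_estimate = est, flag_lawn = lawn
  )
}
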