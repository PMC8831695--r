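#' Read a tidy microplate time-series file
#'
#' Expects the tidy long layout used throughout the package: one row per
#' (time, well, channel) measurement with columns `time_min`, `well`,
#' `channel` (one of `OD600`, `GFP`, `RFP`) and `value`.
#'
#' @param path Path to a CSV file.
#' @return A data.frame with the four validated columns.
#' @export
read_plate <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_min", "well", "channel", "value")
  if (!all(need %in% names(df)))
    stop("plate file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!all(is.finite(df$time_min)) || !all(is.finite(df$value)))
    stop("plate file contains non-finite values", call. = FALSE)
  df[need]
}

#' Read a well-map file
#'
#' One row per well with columns `well`, `strain`, `role` (one of `sample`,
#' `blank_medium`, `autofluorescence_control`, `reference`), `inducer` and
#' `conc_nM`.
#'
#' @param path Path to a CSV file.
#' @return A validated data.frame.
#' @export
read_wellmap <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("well", "strain", "role", "inducer", "conc_nM")
  if (!all(need %in% names(df)))
    stop("well map must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  roles <- c("sample", "blank_medium", "autofluorescence_control", "reference")
  bad <- setdiff(unique(df$role), roles)
  if (length(bad) > 0)
    stop("unknown well roles: ", paste(bad, collapse = ", "), call. = FALSE)
  df[need]
}

# pointwise mean series of a channel over a set of wells, on the common grid
well_mean_series <- function(plate, wells, channel) {
  sub <- plate[plate$well %in% wells & plate$channel == channel, ]
  if (nrow(sub) == 0) return(NULL)
  agg <- stats::aggregate(value ~ time_min, data = sub, FUN = mean)
  agg[order(agg$time_min), ]
}

#' Background-correct a microplate data set
#'
#' Two-step correction. (1) Every channel has the time-pointwise mean of the
#' blank-medium wells subtracted, removing medium absorbance and medium
#' autofluorescence. (2) If autofluorescence-control wells (cells carrying no
#' fluorescent reporter) are present, each fluorescence channel additionally
#' has the control strain's blank-corrected fluorescence subtracted,
#' interpolated as a function of blank-corrected OD600 — cell
#' autofluorescence scales with biomass, not with time, so the lookup is
#' OD-matched. Sample ODs outside the control's OD range are clamped to the
#' nearest control OD with a warning. Negative corrected values are clipped
#' to zero; the number of clipped points is attached as attribute
#' `n_clipped`.
#'
#' @param plate Tidy plate data.frame ([read_plate()] layout).
#' @param wellmap Well map data.frame ([read_wellmap()] layout).
#' @param autofluor Apply the OD-matched autofluorescence correction when
#'   control wells exist. Default `TRUE`.
#' @return The plate data.frame with corrected `value`s, attribute
#'   `n_clipped`.
#' @export
subtract_background <- function(plate, wellmap, autofluor = TRUE) {
  blanks <- wellmap$well[wellmap$role == "blank_medium"]
  if (length(blanks) == 0)
    stop("no blank_medium wells in the well map", call. = FALSE)
  ctrls <- wellmap$well[wellmap$role == "autofluorescence_control"]
  channels <- unique(plate$channel)
  out <- plate
  n_clipped <- 0L

  # step 1: blank-medium subtraction, every channel
  for (ch in channels) {
    bl <- well_mean_series(plate, blanks, ch)
    if (is.null(bl)) next
    idx <- which(out$channel == ch)
    bg <- bl$value[match(out$time_min[idx], bl$time_min)]
    bg[is.na(bg)] <- stats::approx(bl$time_min, bl$value,
                                   xout = out$time_min[idx][is.na(bg)],
                                   rule = 2)$y
    out$value[idx] <- out$value[idx] - bg
  }

  # step 2: OD-matched autofluorescence subtraction for fluorescence channels
  fluo_channels <- setdiff(channels, "OD600")
  if (autofluor && length(ctrls) > 0 && "OD600" %in% channels) {
    ctrl_od <- well_mean_series(out, ctrls, "OD600")
    for (ch in fluo_channels) {
      ctrl_fl <- well_mean_series(out, ctrls, ch)
      if (is.null(ctrl_fl) || is.null(ctrl_od)) next
      od_grid <- ctrl_od$value
      fl_grid <- ctrl_fl$value[match(ctrl_od$time_min, ctrl_fl$time_min)]
      ok <- !is.na(fl_grid)
      od_grid <- od_grid[ok]; fl_grid <- fl_grid[ok]
      o <- order(od_grid)
      od_grid <- od_grid[o]; fl_grid <- fl_grid[o]
      # collapse duplicate OD values to their mean fluorescence
      if (anyDuplicated(od_grid)) {
        agg <- stats::aggregate(fl_grid ~ od_grid, FUN = mean)
        od_grid <- agg$od_grid; fl_grid <- agg$fl_grid
      }
      if (length(od_grid) < 2) next
      non_ctrl <- setdiff(unique(out$well), c(blanks, ctrls))
      for (w in non_ctrl) {
        odw <- out[out$well == w & out$channel == "OD600", ]
        flw_idx <- which(out$well == w & out$channel == ch)
        if (nrow(odw) == 0 || length(flw_idx) == 0) next
        od_at <- odw$value[match(out$time_min[flw_idx], odw$time_min)]
        span <- 0.02 * (max(od_grid) - min(od_grid))
        if (any(od_at > max(od_grid) + span | od_at < min(od_grid) - span,
                na.rm = TRUE))
          warning(sprintf(
            "well %s OD outside autofluorescence-control range; clamping",
            w), call. = FALSE)
        af <- stats::approx(od_grid, fl_grid, xout = od_at, rule = 2)$y
        out$value[flw_idx] <- out$value[flw_idx] - af
      }
      # the controls themselves are fully explained by background
      ctrl_idx <- which(out$well %in% ctrls & out$channel == ch)
      out$value[ctrl_idx] <- 0
    }
  }

  neg <- out$value < 0
  n_clipped <- sum(neg)
  out$value[neg] <- 0
  attr(out, "n_clipped") <- n_clipped
  out
}

# O(1) log-linear R^2 over subwindows via cumulative sums
r2_cumsum <- function(t, y) {
  n <- length(t)
  Sx <- cumsum(t); Sy <- cumsum(y)
  Sxx <- cumsum(t * t); Sxy <- cumsum(t * y); Syy <- cumsum(y * y)
  at <- function(S, i, j) S[j] - if (i > 1) S[i - 1] else 0
  function(i, j) {
    m <- j - i + 1
    sx <- at(Sx, i, j); sy <- at(Sy, i, j)
    sxx <- at(Sxx, i, j); sxy <- at(Sxy, i, j); syy <- at(Syy, i, j)
    vx <- m * sxx - sx * sx
    vy <- m * syy - sy * sy
    if (vx <= 0 || vy <= 0) return(NA_real_)
    (m * sxy - sx * sy)^2 / (vx * vy)
  }
}

#' Select the exponential-growth window of an OD time series
#'
#' Finds the longest contiguous stretch of points whose background-corrected
#' OD lies within a fractional band of the series maximum (default 5--50%,
#' which excludes both the detection floor and the approach to stationary
#' phase) and whose log-linear fit achieves `R^2 >= r2_min` with at least
#' `min_points` points. Ties in length are broken toward the earlier window.
#'
#' @param time_min Time, minutes, strictly increasing.
#' @param od Background-corrected OD600, same length.
#' @param od_min_frac,od_max_frac Fractional OD band relative to `max(od)`.
#'   Defaults 0.05 and 0.5.
#' @param min_points Minimum points in the window. Default 5.
#' @param r2_min Minimum log-linear `R^2`. Default 0.99.
#' @return A list with `start`, `end` (minutes), `idx` (indices into the
#'   series) and `r_squared`. Errors (reporting the best `R^2` found) when no
#'   window qualifies.
#' @export
exponential_window <- function(time_min, od, od_min_frac = 0.05,
                               od_max_frac = 0.5, min_points = 5,
                               r2_min = 0.99) {
  stopifnot(length(time_min) == length(od))
  if (any(diff(time_min) <= 0))
    stop("time must be strictly increasing", call. = FALSE)
  if (sum(od > 0) < 8)
    stop("need >= 8 OD points above the detection floor", call. = FALSE)
  odmax <- max(od)
  in_band <- od >= od_min_frac * odmax & od <= od_max_frac * odmax & od > 0
  runs <- rle(in_band)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  best <- NULL
  best_r2_seen <- -Inf
  for (k in which(runs$values)) {
    i0 <- starts[k]; j0 <- ends[k]
    if (j0 - i0 + 1 < min_points) next
    seg <- i0:j0
    r2f <- r2_cumsum(time_min[seg], log(od[seg]))
    m <- length(seg)
    for (len in seq(m, min_points, by = -1)) {
      if (!is.null(best) && len <= length(best$idx)) break
      for (i in seq_len(m - len + 1)) {
        r2 <- r2f(i, i + len - 1)
        if (!is.na(r2)) best_r2_seen <- max(best_r2_seen, r2)
        if (!is.na(r2) && r2 >= r2_min) {
          idx <- seg[i:(i + len - 1)]
          cand <- list(start = time_min[idx[1]],
                       end = time_min[idx[length(idx)]],
                       idx = idx, r_squared = r2)
          if (is.null(best) ||
              length(cand$idx) > length(best$idx) ||
              (length(cand$idx) == length(best$idx) &&
               cand$start < best$start)) best <- cand
          break  # first (earliest) window of this length in this run
        }
      }
      if (!is.null(best) && length(best$idx) == len) break
    }
  }
  if (is.null(best))
    stop(sprintf(
      "no exponential window found (best R^2 = %.4f over candidate windows)",
      if (is.finite(best_r2_seen)) best_r2_seen else NA_real_),
      call. = FALSE)
  best
}

#' Growth rate from the exponential window
#'
#' Ordinary least-squares slope of `ln(OD)` versus time (in hours) within
#' the selected window.
#'
#' @inheritParams exponential_window
#' @param window A window as returned by [exponential_window()].
#' @return A list with `mu` (1/h) and `r_squared`.
#' @export
growth_rate <- function(time_min, od, window) {
  idx <- window$idx
  if (length(idx) < 3)
    stop("growth window must contain >= 3 points", call. = FALSE)
  if (any(od[idx] <= 0))
    stop("non-positive OD inside the growth window ",
         "(background over-subtraction upstream?)", call. = FALSE)
  t_h <- time_min[idx] / 60
  fit <- stats::lm(log(od[idx]) ~ t_h)
  y <- log(od[idx])
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else NA_real_
  list(mu = unname(stats::coef(fit)[2]), r_squared = r2)
}

#' Per-cell synthesis rate time series
#'
#' Computes `S(t) = dF/dt / OD600(t)`: the numerical time derivative of the
#' background-corrected fluorescence, divided pointwise by the
#' background-corrected OD. The derivative uses central differences at
#' interior points and one-sided differences at the ends. Points with OD
#' below `od_floor` are masked (`NA`) — division by near-zero biomass only
#' amplifies read noise.
#'
#' @param time_min Time, minutes, strictly increasing.
#' @param fluo Background-corrected fluorescence, AU.
#' @param od Background-corrected OD600, aligned.
#' @param od_floor OD detection floor below which points are masked.
#'   Default 0.01.
#' @param smooth Optional odd window width for moving-average smoothing of
#'   the fluorescence before differentiation; 0 (default) disables it.
#' @return Numeric vector `S(t)` in AU·OD^-1·min^-1, `NA` where masked.
#' @export
synthesis_rate <- function(time_min, fluo, od, od_floor = 0.01, smooth = 0) {
  n <- length(time_min)
  stopifnot(length(fluo) == n, length(od) == n)
  if (n < 3) stop("need >= 3 points to differentiate", call. = FALSE)
  if (smooth >= 3) {
    if (smooth %% 2 == 0) stop("smooth width must be odd", call. = FALSE)
    k <- rep(1 / smooth, smooth)
    sm <- stats::filter(fluo, k, sides = 2)
    fluo <- ifelse(is.na(sm), fluo, as.numeric(sm))
  }
  dFdt <- numeric(n)
  dFdt[1] <- (fluo[2] - fluo[1]) / (time_min[2] - time_min[1])
  dFdt[n] <- (fluo[n] - fluo[n - 1]) / (time_min[n] - time_min[n - 1])
  if (n > 2) {
    i <- 2:(n - 1)
    dFdt[i] <- (fluo[i + 1] - fluo[i - 1]) / (time_min[i + 1] - time_min[i - 1])
  }
  S <- dFdt / od
  S[od < od_floor] <- NA_real_
  if (all(is.na(S)))
    stop("all synthesis-rate points masked (OD below floor)", call. = FALSE)
  S
}

#' Reference-normalized per-cell synthesis rate
#'
#' `S_cell = S_ave / S_ave_ref`, where the reference is the mean synthesis
#' rate of a dedicated constitutive reporter strain measured on the same
#' plate and in the same channel. RFP and GFP use distinct reference strains,
#' so the channels must match.
#'
#' @param S_ave Mean synthesis rate of the strain of interest,
#'   AU·OD^-1·min^-1.
#' @param S_ave_ref Mean synthesis rate of the reference strain, same units
#'   and channel (> 0).
#' @param channel,ref_channel Optional channel labels; if both given they
#'   must match.
#' @return Dimensionless `S_cell`.
#' @export
s_cell <- function(S_ave, S_ave_ref, channel = NULL, ref_channel = NULL) {
  if (!is.null(channel) && !is.null(ref_channel) &&
      !identical(channel, ref_channel))
    stop("channel mismatch between sample and reference S_ave", call. = FALSE)
  if (!is.finite(S_ave_ref) || S_ave_ref <= 0)
    stop("reference S_ave must be > 0", call. = FALSE)
  S_ave / S_ave_ref
}

#' Reduce a whole plate to per-well kinetic results
#'
#' End-to-end reduction: background correction, exponential-window selection
#' on each well's OD600, growth-rate fit, per-cell synthesis rates averaged
#' over the window, and normalization to the plate's reference strains.
#'
#' @param plate Tidy plate data.frame ([read_plate()] layout).
#' @param wellmap Well map ([read_wellmap()] layout).
#' @param ref_strains Named character vector mapping fluorescence channel to
#'   the reference strain for that channel.
#'   Default `c(RFP = "J101R", GFP = "J101G")`.
#' @param autofluor Apply autofluorescence-control correction. Default TRUE.
#' @param smooth Odd moving-average width for fluorescence smoothing;
#'   0 disables.
#' @return A data.frame of class `"plate_kinetics"`, one row per sample or
#'   reference well: `well`, `strain`, `role`, `inducer`, `conc_nM`,
#'   `mu_per_h`, `r_squared`, `window_start_min`, `window_end_min`, and
#'   `S_ave_<ch>` / `S_cell_<ch>` per fluorescence channel. Wells whose
#'   window selection fails are reported with `NA` results and a warning.
#' @export
process_plate <- function(plate, wellmap,
                          ref_strains = c(RFP = "J101R", GFP = "J101G"),
                          autofluor = TRUE, smooth = 0) {
  corrected <- subtract_background(plate, wellmap, autofluor = autofluor)
  fluo_channels <- setdiff(unique(plate$channel), "OD600")
  use <- wellmap[wellmap$role %in% c("sample", "reference"), ]
  rows <- vector("list", nrow(use))
  for (i in seq_len(nrow(use))) {
    w <- use$well[i]
    odw <- corrected[corrected$well == w & corrected$channel == "OD600", ]
    odw <- odw[order(odw$time_min), ]
    row <- list(well = w, strain = use$strain[i], role = use$role[i],
                inducer = use$inducer[i], conc_nM = use$conc_nM[i],
                mu_per_h = NA_real_, r_squared = NA_real_,
                window_start_min = NA_real_, window_end_min = NA_real_)
    for (ch in fluo_channels) row[[paste0("S_ave_", ch)]] <- NA_real_
    win <- tryCatch(exponential_window(odw$time_min, odw$value),
                    error = function(e) {
                      warning(sprintf("well %s: %s", w, conditionMessage(e)),
                              call. = FALSE)
                      NULL
                    })
    if (!is.null(win)) {
      gr <- growth_rate(odw$time_min, odw$value, win)
      row$mu_per_h <- gr$mu
      row$r_squared <- gr$r_squared
      row$window_start_min <- win$start
      row$window_end_min <- win$end
      for (ch in fluo_channels) {
        flw <- corrected[corrected$well == w & corrected$channel == ch, ]
        flw <- flw[order(flw$time_min), ]
        if (nrow(flw) == 0) next
        S <- synthesis_rate(flw$time_min, flw$value, odw$value,
                            smooth = smooth)
        row[[paste0("S_ave_", ch)]] <- mean(S[win$idx], na.rm = TRUE)
      }
    }
    rows[[i]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  # channel-matched normalization to the plate's reference strains
  for (ch in fluo_channels) {
    scol <- paste0("S_ave_", ch)
    ccol <- paste0("S_cell_", ch)
    res[[ccol]] <- NA_real_
    refname <- ref_strains[[ch]]
    if (is.null(refname) || is.na(refname)) next
    refvals <- res[[scol]][res$role == "reference" & res$strain == refname]
    refvals <- refvals[is.finite(refvals)]
    if (length(refvals) == 0) next
    res[[ccol]] <- res[[scol]] / mean(refvals)
  }
  class(res) <- c("plate_kinetics", "data.frame")
  res
}

#' Aggregate kinetic results over biological replicates
#'
#' Collapses per-well results to mean and standard error of the mean per
#' (strain, inducer, concentration) condition, the level at which transfer
#' curves are usually reported.
#'
#' @param kinetics A [process_plate()] result.
#' @param columns Result columns to aggregate. Defaults to all `mu_per_h` /
#'   `S_cell_*` columns present.
#' @return A data.frame keyed by strain, inducer and conc_nM with
#'   `<col>_mean`, `<col>_sem` and `n_replicates`.
#' @export
aggregate_replicates <- function(kinetics, columns = NULL) {
  if (is.null(columns))
    columns <- intersect(c("mu_per_h", grep("^S_cell_", names(kinetics),
                                            value = TRUE)),
                         names(kinetics))
  key <- interaction(kinetics$strain, kinetics$inducer, kinetics$conc_nM,
                     drop = TRUE)
  groups <- split(seq_len(nrow(kinetics)), key)
  out <- lapply(groups, function(idx) {
    row <- data.frame(strain = kinetics$strain[idx[1]],
                      inducer = kinetics$inducer[idx[1]],
                      conc_nM = kinetics$conc_nM[idx[1]],
                      n_replicates = length(idx))
    for (cn in columns) {
      v <- kinetics[[cn]][idx]
      v <- v[is.finite(v)]
      row[[paste0(cn, "_mean")]] <- if (length(v)) mean(v) else NA_real_
      row[[paste0(cn, "_sem")]] <-
        if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_
    }
    row
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' @export
print.plate_kinetics <- function(x, ...) {
  cat(sprintf("Plate kinetics: %d wells (%d sample, %d reference)\n",
              nrow(x), sum(x$role == "sample"), sum(x$role == "reference")))
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}
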