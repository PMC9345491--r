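#' Probe every unit with optimal drifting and rotating gratings
#'
#' Each unit's preferred grating is determined first — by default
#' empirically, as in electrophysiology: a family of static gratings spanning
#' orientation, spatial frequency and phase is presented and the
#' argmax-response parameters are taken per unit (`optimal = "gabor"` instead
#' uses log-Gabor fits of the first-layer kernels / back-projected
#' second-layer kernels). Every unit is then swept with a drifting grating
#' (one 360 degree phase cycle) and a rotating grating (one 180 degree
#' orientation cycle) at its preferred parameters; sweeps shared by several
#' units are inferred once. The per-unit steady-state tuning curves yield
#' F1/F0 under both protocols, the rectified-sine chi indices, and the
#' rotating-curve HWHH.
#'
#' @param fit a fitted `"sdpc"` model.
#' @param layers which layers to probe.
#' @param images image batch for the second-layer back-projection (only
#'   needed with `optimal = "gabor"`).
#' @param samples_per_cycle frames per sweep.
#' @param infer_iters inference iteration cap per frame batch.
#' @param whiten_probes whiten the probe stimuli with the training filter.
#' @param mask_diameter circular mask diameter in pixels (the receptive-field
#'   size of the units).
#' @param protocols which grating protocols to run (`"drift"`, `"rotate"`);
#'   chi and HWHH columns are only filled for protocols that ran.
#' @param optimal `"empirical"` (argmax over the grating grid) or `"gabor"`
#'   (log-Gabor fits assign the preferred parameters).
#' @param theta_grid,f0_grid,phase_grid the grating family searched in
#'   empirical mode.
#' @param backprojection optionally, a precomputed [backproject()] result
#'   (implies gabor-based preferences for layer 2).
#' @return a data frame with one row per probed unit.
#' @export
probe_population <- function(fit, layers = c(1L, 2L), images = NULL,
                             samples_per_cycle = 32L, infer_iters = 60L,
                             whiten_probes = TRUE, mask_diameter = 14,
                             protocols = c("drift", "rotate"),
                             optimal = c("empirical", "gabor"),
                             theta_grid = seq(0, 165, by = 15),
                             f0_grid = c(0.08, 0.12, 0.18, 0.26),
                             phase_grid = c(0, 90, 180, 270),
                             backprojection = NULL) {
  optimal <- match.arg(optimal)
  if (!is.null(backprojection)) optimal <- "gabor"
  size <- fit$in_dim[1]
  etas <- auto_steps(fit, fit$in_dim)
  M_of <- vapply(fit$layers, `[[`, 0L, "n_units")
  safe_fit <- function(k) tryCatch(fit_log_gabor(k), error = function(e) NULL)

  # ---- preferred parameters per unit
  pref <- list()
  if (optimal == "gabor") {
    for (layer in layers) {
      fits <- if (layer == 1L) {
        kern <- fit$kernels[[1]]
        lapply(seq_len(dim(kern)[4]), function(m) safe_fit(kern[, , 1, m]))
      } else {
        if (is.null(backprojection)) {
          if (is.null(images))
            stop("gabor-based layer-2 preferences need 'images' (or 'backprojection')")
          backprojection <- backproject(fit, images)
        }
        V <- backprojection$kernels
        lapply(seq_len(dim(V)[4]), function(m) safe_fit(V[, , 1, m]))
      }
      pref[[as.character(layer)]] <- data.frame(
        unit = seq_along(fits),
        theta = vapply(fits, function(f) if (is.null(f)) NA_real_ else f$theta, 0),
        f0 = vapply(fits, function(f) if (is.null(f)) NA_real_
                    else min(max(f$f0, 0.04), 0.45), 0),
        phi = vapply(fits, function(f) if (is.null(f)) NA_real_ else f$phi, 0),
        peak = NA_real_,
        gabor_hwhh = vapply(fits, function(f) if (is.null(f)) NA_real_ else f$hwhh, 0),
        gabor_residual = vapply(fits, function(f) if (is.null(f)) NA_real_
                                else f$residual, 0))
    }
  } else {
    grid <- expand.grid(theta = theta_grid, f0 = f0_grid, phi = phase_grid)
    frames <- array(0, dim = c(size, size, nrow(grid)))
    for (i in seq_len(nrow(grid)))
      frames[, , i] <- make_grating(size, grid$theta[i], grid$phi[i],
                                    grid$f0[i], mask_diameter)
    if (whiten_probes)
      frames <- array(whiten_images(frames), dim = dim(frames))
    best <- lapply(layers, function(l) list(val = rep(-Inf, M_of[l]),
                                            idx = rep(1L, M_of[l])))
    names(best) <- as.character(layers)
    for (chunk in split(seq_len(nrow(grid)),
                        ceiling(seq_len(nrow(grid)) / 32))) {
      st <- sdpc_infer(frames[, , chunk, drop = FALSE], fit,
                       max_iters = infer_iters, etas = etas)
      for (layer in layers) {
        g <- st$gamma[[layer]]
        M <- M_of[layer]
        for (j in seq_along(chunk)) {
          for (m in seq_len(M)) {
            v <- max(g[, , (j - 1L) * M + m])
            if (v > best[[as.character(layer)]]$val[m]) {
              best[[as.character(layer)]]$val[m] <- v
              best[[as.character(layer)]]$idx[m] <- chunk[j]
            }
          }
        }
      }
    }
    # log-Gabor descriptors of the first-layer kernels come along for free
    g1 <- if (1L %in% layers) {
      kern <- fit$kernels[[1]]
      lapply(seq_len(dim(kern)[4]), function(m) safe_fit(kern[, , 1, m]))
    } else NULL
    for (layer in layers) {
      b <- best[[as.character(layer)]]
      responsive <- b$val > 1e-9
      pref[[as.character(layer)]] <- data.frame(
        unit = seq_len(M_of[layer]),
        theta = ifelse(responsive, grid$theta[b$idx], NA_real_),
        f0 = ifelse(responsive, grid$f0[b$idx], NA_real_),
        phi = ifelse(responsive, grid$phi[b$idx], NA_real_),
        peak = ifelse(responsive, b$val, 0),
        gabor_hwhh = if (layer == 1L && !is.null(g1))
          vapply(g1, function(f) if (is.null(f)) NA_real_ else f$hwhh, 0)
          else NA_real_,
        gabor_residual = if (layer == 1L && !is.null(g1))
          vapply(g1, function(f) if (is.null(f)) NA_real_ else f$residual, 0)
          else NA_real_)
    }
  }

  # ---- measurement sweeps, shared across units with the same parameters
  out <- list()
  for (layer in layers) {
    p <- pref[[as.character(layer)]]
    n <- nrow(p)
    cols <- list(
      F0_drift = rep(NA_real_, n), F1_drift = rep(NA_real_, n),
      f1f0_drift = rep(NA_real_, n), responsive_drift = rep(FALSE, n),
      chi_phi = rep(NA_real_, n),
      F0_rotate = rep(NA_real_, n), F1_rotate = rep(NA_real_, n),
      f1f0_rotate = rep(NA_real_, n), responsive_rotate = rep(FALSE, n),
      chi_theta = rep(NA_real_, n), hwhh_curve = rep(NA_real_, n))
    probe_ok <- !is.na(p$theta)
    for (mode in protocols) {
      key <- if (mode == "drift") paste(p$theta, p$f0)
             else paste(p$f0, round(p$phi))
      for (k in unique(key[probe_ok])) {
        members <- which(probe_ok & key == k)
        first <- members[1]
        sq <- grating_sequence(mode, size,
                               orientation = if (mode == "drift") p$theta[first] else 0,
                               phase = p$phi[first], frequency = p$f0[first],
                               mask_diameter = mask_diameter,
                               samples_per_cycle = samples_per_cycle,
                               whiten = whiten_probes)
        state <- sdpc_infer(array(sq, dim = dim(sq)), fit,
                            max_iters = infer_iters, etas = etas)
        for (m in members) {
          curve <- withCallingHandlers(
            tuning_curve(fit, sq, layer = layer, unit = m, state = state),
            warning = function(w) invokeRestart("muffleWarning"))
          mr <- modulation_ratio(curve)
          chi <- tryCatch(fit_rectified_sine(curve)$chi,
                          error = function(e) NA_real_)
          resp <- mr$classification != "nonresponsive"
          if (mode == "drift") {
            cols$F0_drift[m] <- mr$F0; cols$F1_drift[m] <- mr$F1
            cols$f1f0_drift[m] <- mr$f1f0
            cols$responsive_drift[m] <- resp
            cols$chi_phi[m] <- chi
          } else {
            cols$F0_rotate[m] <- mr$F0; cols$F1_rotate[m] <- mr$F1
            cols$f1f0_rotate[m] <- mr$f1f0
            cols$responsive_rotate[m] <- resp
            cols$chi_theta[m] <- chi
            cols$hwhh_curve[m] <- if (resp) hwhh(curve) else NA_real_
          }
        }
      }
      # silent units get explicit zero responses
      for (m in which(!probe_ok)) {
        if (mode == "drift") {
          cols$F0_drift[m] <- 0; cols$F1_drift[m] <- 0
        } else {
          cols$F0_rotate[m] <- 0; cols$F1_rotate[m] <- 0
        }
      }
    }
    out[[as.character(layer)]] <- cbind(data.frame(layer = layer), p,
                                        as.data.frame(cols))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Population summary statistics
#'
#' Aggregates per-unit probe results into the population measures: `R_phi`
#' and `R_theta` (the percentage of responsive units with F1/F0 < 1 under
#' the drifting and rotating protocols), the chi distributions (median and
#' MAD), a paired one-tailed Wilcoxon signed-rank test of `chi_phi <
#' chi_theta` (phase invariance exceeding orientation invariance), and, when
#' a first-layer LHI map is supplied, the ordinary least-squares regression
#' of orientation-tuning HWHH on LHI.
#'
#' @param units data frame from [probe_population()] (minimally: `layer`,
#'   `f1f0_drift`; the other columns are used when present).
#' @param lhi optional `"lhi_map"` (or vector of per-unit LHI values, in
#'   first-layer unit order) for the HWHH-vs-LHI regression.
#' @return a `"population_summary"`: `per_layer` data frame and `regression`
#'   list (slope, intercept, p_value) or `NULL`.
#' @export
population_summary <- function(units, lhi = NULL) {
  stopifnot(is.data.frame(units), nrow(units) > 0)
  getcol <- function(d, nm) if (nm %in% names(d)) d[[nm]] else rep(NA, nrow(d))
  per <- lapply(sort(unique(units$layer)), function(ly) {
    d <- units[units$layer == ly, , drop = FALSE]
    fd <- getcol(d, "f1f0_drift"); fr <- getcol(d, "f1f0_rotate")
    rd <- !is.na(fd); rr <- !is.na(fr)
    cp <- getcol(d, "chi_phi"); ct <- getcol(d, "chi_theta")
    ok <- !is.na(cp) & !is.na(ct)
    p <- NA_real_
    if (sum(ok) >= 3) {
      diffs <- cp[ok] - ct[ok]
      p <- if (all(diffs == 0)) 0.5 else
        suppressWarnings(wilcox.test(cp[ok], ct[ok], paired = TRUE,
                                     alternative = "less")$p.value)
    }
    data.frame(layer = ly, n = nrow(d),
               n_nonresponsive_drift = sum(!rd),
               n_nonresponsive_rotate = sum(!rr),
               R_phi = if (any(rd)) 100 * mean(fd[rd] < 1) else NA_real_,
               R_theta = if (any(rr)) 100 * mean(fr[rr] < 1) else NA_real_,
               chi_phi_median = median(cp, na.rm = TRUE),
               chi_phi_mad = mad(cp, na.rm = TRUE),
               chi_theta_median = median(ct, na.rm = TRUE),
               chi_theta_mad = mad(ct, na.rm = TRUE),
               p_chi_phi_lt_theta = p)
  })
  per <- do.call(rbind, per)
  regression <- NULL
  if (!is.null(lhi)) {
    lv <- if (inherits(lhi, "lhi_map")) {
      if (is.matrix(lhi$lhi)) as.numeric(t(lhi$lhi)) else lhi$lhi
    } else as.numeric(lhi) # row-major unit order for grids
    d1 <- units[units$layer == 1L, , drop = FALSE]
    hw <- getcol(d1, "hwhh_curve")
    if (all(is.na(hw))) hw <- getcol(d1, "gabor_hwhh")
    if (nrow(d1) == length(lv) && sum(!is.na(hw)) >= 3) {
      fitlm <- lm(hw ~ lv)
      sm <- summary(fitlm)$coefficients
      regression <- list(slope = unname(sm[2, 1]),
                         intercept = unname(sm[1, 1]),
                         p_value = unname(sm[2, 4]))
    }
  }
  structure(list(per_layer = per, regression = regression),
            class = "population_summary")
}

#' @export
print.population_summary <- function(x, ...) {
  for (i in seq_len(nrow(x$per_layer))) {
    r <- x$per_layer[i, ]
    cat(sprintf(
      "layer %d: R_phi = %.1f%%, R_theta = %.1f%% (n = %d; nonresponsive %d/%d)\n",
      r$layer, r$R_phi, r$R_theta, r$n, r$n_nonresponsive_drift,
      r$n_nonresponsive_rotate))
    cat(sprintf(
      "  chi_phi = %.2f +/- %.2f, chi_theta = %.2f +/- %.2f (median +/- MAD), one-tailed signed-rank p = %.3g\n",
      r$chi_phi_median, r$chi_phi_mad, r$chi_theta_median, r$chi_theta_mad,
      r$p_chi_phi_lt_theta))
  }
  if (!is.null(x$regression))
    cat(sprintf("HWHH ~ LHI: slope %.2f deg/unit (p = %.3g)\n",
                x$regression$slope, x$regression$p_value))
  invisible(x)
}
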