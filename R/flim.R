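# TCSPC decay fitting, short-lifetime fraction, fluorescence anisotropy
# and photoselection sector statistics.

#' Extract one pixel (or the pooled ROI) decay histogram
#'
#' @param dataset A `flim_dataset`.
#' @param pixels Optional pixel indices to pool; default all.
#' @return A `decay_histogram`: `time_ps`, `counts_parallel`,
#'   `counts_perpendicular`, `g_factor`, `laser_power`, `bin_ps`.
#' @export
decay_histogram <- function(dataset, pixels = NULL) {
  pixels <- pixels %||% seq_len(nrow(dataset$parallel))
  structure(list(time_ps = dataset$time_ps,
                 counts_parallel = colSums(dataset$parallel[pixels, , drop = FALSE]),
                 counts_perpendicular = colSums(dataset$perpendicular[pixels, , drop = FALSE]),
                 g_factor = dataset$g_factor, laser_power = dataset$laser_power,
                 bin_ps = dataset$bin_ps),
            class = "decay_histogram")
}

# Per-bin model counts for exponential components (amplitudes are counts
# in the first bin of each component).
decay_model <- function(par, t, n_components, background) {
  mu <- rep(if (background) par[2 * n_components + 1] else 0, length(t))
  for (k in seq_len(n_components)) {
    mu <- mu + par[2 * k - 1] * exp(-t / par[2 * k])
  }
  mu
}

# Deterministic initialization from log-linear tail slopes.
init_decay <- function(t, y, n_components, background) {
  pos <- y > 0
  if (sum(pos) < 4) stop_data("too few positive bins to initialize the decay fit")
  n <- length(t)
  late <- which(pos & t >= stats::quantile(t, 0.5))
  if (length(late) < 3) late <- which(pos)
  sl <- stats::lm.fit(cbind(1, t[late]), log(y[late]))$coefficients
  tau_long <- max(-1 / min(sl[2], -1e-9), 3 * diff(t)[1])
  a_long <- exp(sl[1])
  par <- NULL
  if (n_components == 1) {
    par <- c(a_long, tau_long)
  } else {
    resid <- y - a_long * exp(-t / tau_long)
    early <- which(resid > 0 & t <= stats::quantile(t, 0.2))
    if (length(early) >= 3) {
      ss <- stats::lm.fit(cbind(1, t[early]), log(resid[early]))$coefficients
      tau_short <- max(-1 / min(ss[2], -1e-9), diff(t)[1] / 2)
      a_short <- exp(ss[1])
    } else {
      tau_short <- tau_long / 10
      a_short <- max(y[1] - a_long, a_long / 10)
    }
    if (tau_short >= tau_long) tau_short <- tau_long / 10
    par <- c(a_short, tau_short, a_long, tau_long)
  }
  if (background) par <- c(par, max(min(y[y >= 0]), 1e-3))
  par
}

#' Fit an exponential decay model to a TCSPC histogram
#'
#' Maximum-likelihood fit under Poisson statistics (minimizing the
#' Poisson deviance) of `sum_k a_k exp(-t / tau_k) (+ background)` to
#' the tail of a photon-arrival histogram. The fit window starts two
#' bins after the histogram peak (tail fit; no instrument-response
#' deconvolution). Components are relabeled so `tau_short < tau_long`
#' and the short-component amplitude fraction is reported.
#'
#' @param histogram A `decay_histogram` (or `flim_dataset`, pooled over
#'   all pixels).
#' @param n_components 1 or 2.
#' @param fit_window Optional `c(t_start, t_end)` ps overriding the
#'   default tail window.
#' @param channel `"sum"` (default; parallel + perpendicular),
#'   `"parallel"` or `"perpendicular"`.
#' @param background Include a constant background term (default TRUE).
#' @param min_counts Minimum total counts in the window (default 100).
#' @return A `biexp_fit`: `tau_short`, `tau_long`, `amp_short`,
#'   `amp_long`, `f_short`, `background`, `deviance`, `converged`,
#'   `n_photons`. For `n_components = 1` the single component is
#'   reported as the long one and `f_short = 0`.
#' @export
fit_decay <- function(histogram, n_components = 2, fit_window = NULL,
                      channel = c("sum", "parallel", "perpendicular"),
                      background = TRUE, min_counts = 100) {
  channel <- match.arg(channel)
  if (inherits(histogram, "flim_dataset")) histogram <- decay_histogram(histogram)
  if (!n_components %in% c(1, 2)) stop_domain("n_components must be 1 or 2")
  y <- switch(channel,
              sum = histogram$counts_parallel + histogram$counts_perpendicular,
              parallel = histogram$counts_parallel,
              perpendicular = histogram$counts_perpendicular)
  t <- histogram$time_ps
  if (is.null(fit_window)) {
    peak <- which.max(y)
    from <- min(peak + 2L, length(t))
    fit_window <- c(t[from], t[length(t)])
  }
  keep <- t >= fit_window[1] & t <= fit_window[2]
  t0 <- t[keep] - t[keep][1]
  yy <- y[keep]
  n_photons <- sum(yy)
  if (n_photons < min_counts) {
    stop_data("insufficient counts in the fit window (", round(n_photons),
              " < ", min_counts, ")")
  }
  par0 <- init_decay(t0, yy, n_components, background)
  nll <- function(lp) {
    par <- exp(lp)
    mu <- decay_model(par, t0, n_components, background)
    mu <- pmax(mu, 1e-12)
    sum(mu - yy * log(mu))
  }
  opt <- stats::optim(log(pmax(par0, 1e-8)), nll, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  # polish with Nelder-Mead in case BFGS stalls on a kink
  opt2 <- stats::optim(opt$par, nll, method = "Nelder-Mead",
                       control = list(maxit = 2000, reltol = 1e-12))
  if (opt2$value < opt$value) opt <- opt2
  par <- exp(opt$par)
  bg <- if (background) par[2 * n_components + 1] else 0
  # convert fitted per-bin counts to continuous decay amplitudes at the
  # histogram origin: undo the fit-window offset and the bin integration
  # (a bin at t holds a tau (1 - e^(-dt/tau)) e^(-t/tau) photons per
  # unit amplitude)
  dt <- histogram$bin_ps
  t_offset <- t[keep][1] - t[1]
  cont_amp <- function(c_k, tau_k) {
    c_k * exp(t_offset / tau_k) / (tau_k * (1 - exp(-dt / tau_k)))
  }
  if (n_components == 1) {
    fit <- list(tau_short = NA_real_, tau_long = par[2], amp_short = 0,
                amp_long = cont_amp(par[1], par[2]), f_short = 0)
  } else {
    comps <- matrix(par[1:4], ncol = 2)   # rows: amp, tau
    o <- order(comps[2, ])
    amp <- cont_amp(comps[1, o], comps[2, o])
    tau <- comps[2, o]
    fit <- list(tau_short = tau[1], tau_long = tau[2],
                amp_short = amp[1], amp_long = amp[2],
                f_short = amp[1] / (amp[1] + amp[2]))
  }
  mu <- pmax(decay_model(par, t0, n_components, background), 1e-12)
  dev <- 2 * sum(ifelse(yy > 0, yy * log(yy / mu), 0) - (yy - mu))
  # a two-component fit is degenerate when the lifetimes are within 10%
  # of each other or the short component is faster than the bin width
  # (sub-resolution: its extrapolated amplitude is meaningless)
  degenerate <- n_components == 2 && is.finite(fit$tau_short) &&
    ((fit$tau_long - fit$tau_short) / fit$tau_long < 0.1 ||
       fit$tau_short < dt)
  structure(c(fit, list(background = bg, deviance = dev,
                        converged = opt$convergence == 0,
                        degenerate = degenerate,
                        n_photons = n_photons, fit_window = fit_window)),
            class = "biexp_fit")
}

#' @export
print.biexp_fit <- function(x, ...) {
  cat(sprintf("<biexp_fit> tau = %.0f / %.0f ps, f_short = %.3f (%d photons)\n",
              x$tau_short, x$tau_long, x$f_short, round(x$n_photons)))
  invisible(x)
}

#' Short-lifetime amplitude fraction
#'
#' `amp_short / (amp_short + amp_long)` of a converged two-component
#' fit - the amplitude (population) fraction of the fast, carotenoid-
#' attributed decay component.
#'
#' @param fit A `biexp_fit` with two components.
#' @return The fraction in \[0, 1\].
#' @export
short_fraction <- function(fit) {
  if (is.na(fit$tau_short)) stop_data("short_fraction requires a two-component fit")
  if (isTRUE(fit$degenerate)) {
    warning("lifetimes within 10%: short fraction poorly defined")
  }
  fit$f_short
}

#' Fluorescence anisotropy
#'
#' `r = (I_par - G I_perp) / (I_par + 2 G I_perp)`, the standard
#' polarization contrast with instrumental correction factor G.
#' Vectorized over intensities.
#'
#' @param i_parallel,i_perpendicular Non-negative intensities.
#' @param g_factor Correction factor G (> 0, default 1).
#' @return Anisotropy value(s); in \[-0.5, 1\] for non-negative input
#'   with G = 1.
#' @export
anisotropy <- function(i_parallel, i_perpendicular, g_factor = 1) {
  if (g_factor <= 0) stop_domain("g_factor must be > 0")
  if (any(i_parallel < 0 | i_perpendicular < 0, na.rm = TRUE)) {
    stop_domain("intensities must be >= 0")
  }
  denom <- i_parallel + 2 * g_factor * i_perpendicular
  if (any(denom == 0, na.rm = TRUE)) {
    stop_domain("undefined anisotropy: zero total intensity")
  }
  (i_parallel - g_factor * i_perpendicular) / denom
}

#' Sector statistics of an axon cross-section
#'
#' Splits an annulus into four sectors centered on the image axes
#' (left/right along x, top/bottom along y) and reports per-sector
#' photon totals, photon-weighted mean intensity and pooled anisotropy.
#' The left+right versus top+bottom intensity contrast is the
#' photoselection signature of radially oriented (transmembrane)
#' chromophores under horizontal excitation polarization.
#'
#' @param dataset A `flim_dataset`.
#' @param center Length-2 center in pixels; default image center.
#' @param inner_px,outer_px Annulus radii in pixels; default from the
#'   intensity-weighted radius spread.
#' @return List with `sectors` (data frame: `sector`, `n_pixels`,
#'   `photons`, `mean_intensity`, `anisotropy`) and
#'   `lr_tb_intensity_ratio` (pooled left+right over top+bottom mean
#'   intensity).
#' @export
sector_statistics <- function(dataset, center = NULL, inner_px = NULL,
                              outer_px = NULL) {
  nx <- dataset$nx; ny <- dataset$ny
  center <- center %||% c((nx + 1) / 2, (ny + 1) / 2)
  ix <- rep(seq_len(nx), times = ny)
  iy <- rep(seq_len(ny), each = nx)
  dx <- ix - center[1]; dy <- iy - center[2]
  rr <- sqrt(dx^2 + dy^2)
  i_par <- rowSums(dataset$parallel)
  i_perp <- rowSums(dataset$perpendicular)
  tot <- i_par + i_perp
  if (is.null(inner_px) || is.null(outer_px)) {
    w <- tot / max(sum(tot), 1)
    r_mean <- sum(rr * w)
    r_sd <- sqrt(max(sum(w * (rr - r_mean)^2), 1e-12))
    inner_px <- inner_px %||% max(r_mean - 3 * r_sd, 0)
    outer_px <- outer_px %||% (r_mean + 3 * r_sd)
  }
  if (outer_px > max(rr)) outer_px <- max(rr)
  on_ann <- rr >= inner_px & rr <= outer_px & rr > 0
  ang <- atan2(dy, dx)
  sector <- character(length(ang))
  sector[abs(ang) <= pi / 4] <- "right"
  sector[abs(ang) >= 3 * pi / 4] <- "left"
  sector[ang > pi / 4 & ang < 3 * pi / 4] <- "top"
  sector[ang < -pi / 4 & ang > -3 * pi / 4] <- "bottom"
  rows <- lapply(c("left", "right", "top", "bottom"), function(s) {
    sel <- on_ann & sector == s
    n <- sum(sel)
    if (n == 0 || sum(tot[sel]) == 0) {
      return(data.frame(sector = s, n_pixels = n, photons = sum(tot[sel]),
                        mean_intensity = if (n) mean(tot[sel]) else NA_real_,
                        anisotropy = NA_real_))
    }
    data.frame(sector = s, n_pixels = n, photons = sum(tot[sel]),
               mean_intensity = mean(tot[sel]),
               anisotropy = anisotropy(sum(i_par[sel]), sum(i_perp[sel]),
                                       dataset$g_factor))
  })
  sectors <- do.call(rbind, rows)
  lr <- sectors$mean_intensity[sectors$sector %in% c("left", "right")]
  tb <- sectors$mean_intensity[sectors$sector %in% c("top", "bottom")]
  ratio <- if (all(is.finite(tb)) && mean(tb) > 0) mean(lr) / mean(tb) else Inf
  list(sectors = sectors, lr_tb_intensity_ratio = ratio,
       annulus_px = c(inner = inner_px, outer = outer_px))
}

#' Laser-power trend of the short-lifetime fraction
#'
#' Weighted least-squares line of `f_short` against laser power, with a
#' 95% confidence interval on the slope. A slope interval containing
#' zero is the quantitative statement that the photoselected xanthophyll
#' pool is insensitive to the scanning intensity.
#'
#' @param powers Laser powers (>= 3 distinct values).
#' @param f_short Short-lifetime amplitude fractions per power.
#' @param se Optional standard errors for weighting (weights 1/se^2).
#' @return List with `slope`, `ci` (length 2), `table` (per-power data
#'   frame) and the underlying `lm` fit.
#' @export
power_trend <- function(powers, f_short, se = NULL) {
  if (length(unique(powers)) < 3) {
    stop_data("power_trend requires >= 3 distinct powers")
  }
  if (length(f_short) != length(powers)) {
    stop_data("f_short and powers must have equal length")
  }
  w <- if (!is.null(se)) 1 / se^2 else rep(1, length(powers))
  fit <- stats::lm(f_short ~ powers, weights = w)
  ci <- stats::confint(fit, "powers", level = 0.95)
  list(slope = unname(stats::coef(fit)["powers"]),
       ci = c(ci[1], ci[2]),
       table = data.frame(power = powers, f_short = f_short,
                          se = se %||% NA_real_),
       fit = fit)
}
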