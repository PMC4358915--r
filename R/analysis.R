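#' Pool depletion series from trajectories
#'
#' Counts the particles inside the corral (x below the corral boundary) at
#' every snapshot and converts the count to a lipid concentration
#' percentage via the area per lipid, then averages over replicas.  438
#' spheres in a 475 x 1000 A corral at 65 A^2 per lipid give the initial
#' 6%.
#'
#' @param traj A `corral_trajectories` from [run_protocol()].
#' @param area_per_lipid A^2 (default 65).
#' @return An object of class `depletion_series`: `times` (ps), `mean`
#'   (%), `per_replica` (frames x replicas), `n_replicas`, `c0` (initial
#'   mean concentration).
#' @export
depletion_series <- function(traj, area_per_lipid = 65) {
  stopifnot(inherits(traj, "corral_trajectories"))
  geom <- traj$geometry
  corral_area <- (geom$corral_boundary_x - geom$box_x_lo) *
    (geom$box_y_hi - geom$box_y_lo)
  per <- sapply(traj$replicas, function(run) {
    if (is.null(run$x)) stop("trajectory has no snapshots")
    rowSums(run$x < geom$corral_boundary_x)
  })
  per <- matrix(per, nrow = length(traj$times))
  conc <- 100 * per * area_per_lipid / corral_area
  structure(list(times = traj$times, mean = rowMeans(conc),
                 per_replica = conc, n_replicas = ncol(conc),
                 c0 = mean(conc[1, ]), area_per_lipid = area_per_lipid,
                 corral_area = corral_area),
            class = "depletion_series")
}

#' Fit a stretched exponential to a depletion curve
#'
#' Least-squares fit of
#' `C(t) = (C0 - Cinf) exp[-(t/tau)^beta] + Cinf` with `C0` fixed,
#' using Levenberg-Marquardt with multi-start initialization over
#' `beta in {0.4, 0.7, 1.0, 1.3}`; `tau` starts from the time at which
#' the curve first crosses halfway to the plateau guess, and the plateau
#' guess is the mean of the final tenth of the curve.  The best residual
#' wins; ties go to the smallest beta.
#'
#' Curves that do not decay over the simulated span (complete blockade)
#' are flagged rather than force-fitted: the fit is marked
#' `blockade = TRUE` when the fitted mean relaxation time exceeds 100
#' times the simulated span, or when the curve shows essentially no decay.
#'
#' @param series A [depletion_series()] (or [make_decay_curve()] output).
#' @param c0 Fixed initial concentration, % (default 6).
#' @return An object of class `stretched_exp_fit` with elements `c0`,
#'   `c_inf`, `tau`, `beta`, `mean_tau`, `converged`, `blockade`,
#'   `residual_norm`.
#' @export
fit_stretched_exponential <- function(series, c0 = 6) {
  tt <- series$times
  cc <- series$mean
  keep <- tt > 0 | seq_along(tt) == 1
  if (length(tt) < 10) stop("need at least 10 time points")
  span <- max(tt)
  tail_mean <- mean(cc[tt >= 0.9 * span])
  head_mean <- mean(cc[seq_len(max(2, ceiling(length(cc) / 20)))])
  decayed <- (head_mean - tail_mean) > 0.02 * c0
  best <- NULL
  if (decayed) {
    cinf0 <- max(tail_mean, 1e-3)
    half <- (c0 + cinf0) / 2
    icross <- which(cc <= half)[1]
    tau0 <- if (is.na(icross)) span / 2 else max(tt[icross], tt[2])
    for (beta0 in c(0.4, 0.7, 1.0, 1.3)) {
      fit <- tryCatch(
        minpack.lm::nlsLM(
          cc ~ (c0 - cinf) * exp(-(tt / tau)^beta) + cinf,
          start = list(cinf = cinf0, tau = tau0, beta = beta0),
          lower = c(0, 1e-12, 0.05), upper = c(c0, Inf, 2),
          control = minpack.lm::nls.lm.control(maxiter = 500)),
        error = function(e) NULL)
      if (is.null(fit)) next
      rn <- sqrt(sum(residuals(fit)^2))
      if (is.null(best) || rn < best$rn - 1e-12 ||
          (abs(rn - best$rn) <= 1e-12 && coef(fit)[["beta"]] < best$beta)) {
        cf <- coef(fit)
        best <- list(cinf = cf[["cinf"]], tau = cf[["tau"]],
                     beta = cf[["beta"]], rn = rn)
      }
    }
  }
  if (is.null(best)) {
    return(structure(list(c0 = c0, c_inf = tail_mean, tau = Inf, beta = NA,
                          mean_tau = Inf, converged = FALSE,
                          blockade = !decayed, residual_norm = NA),
                     class = "stretched_exp_fit"))
  }
  mt <- mean_relaxation_time(best$tau, best$beta)
  structure(list(c0 = c0, c_inf = best$cinf, tau = best$tau,
                 beta = best$beta, mean_tau = mt, converged = TRUE,
                 blockade = mt > 100 * span, residual_norm = best$rn),
            class = "stretched_exp_fit")
}

#' Mean relaxation time of a stretched exponential
#'
#' `<tau> = (tau / beta) Gamma(1 / beta)`; equals `tau` for beta = 1 and
#' `2 tau` for beta = 0.5.
#'
#' @param tau Relaxation time (> 0).
#' @param beta Stretching exponent (> 0).
#' @return Mean relaxation time in the units of `tau`.
#' @export
mean_relaxation_time <- function(tau, beta) {
  if (any(beta <= 0)) stop("beta must be positive")
  if (any(tau <= 0)) stop("tau must be positive")
  (tau / beta) * gamma(1 / beta)
}

#' Concentration relaxation time ratio
#'
#' `xi = <tau_free> / <tau>`: 1 for free diffusion, 0 for complete
#' blockade (fits flagged as blockade report 0).
#'
#' @param fit Fit for the fenced system ([fit_stretched_exponential()]).
#' @param free_fit Fit for free diffusion.
#' @return Dimensionless ratio.
#' @export
relaxation_ratio <- function(fit, free_fit) {
  if (!free_fit$converged) stop("free-diffusion fit did not converge")
  if (fit$blockade) return(0)
  if (!fit$converged) stop("fenced fit did not converge and is not a blockade")
  if (fit$mean_tau <= 0) stop("mean relaxation time must be positive")
  free_fit$mean_tau / fit$mean_tau
}

#' 1D potential of mean force by Boltzmann inversion
#'
#' `W(x) = -kB T ln[C_eq(x) / C_ref]` from the equilibrium concentration
#' profile (positive where the lipid is depleted).  Bins with zero counts
#' are capped at `cap` and flagged.
#'
#' @param traj A `corral_trajectories` sampled at equilibrium.
#' @param bin_width A (default 5).
#' @param c_ref Reference concentration, % (default 2, the uniform bulk).
#' @param area_per_lipid A^2.
#' @param burn_in Fraction of frames discarded from the front.
#' @param temperature K.
#' @param cap Cap for empty bins, kcal/mol.
#' @return Data frame with `x` (bin centres), `concentration` (%), `w`
#'   (kcal/mol), `empty` (logical); attribute `stationary` reports a
#'   first-half/second-half pool-count consistency check.
#' @export
pmf_1d <- function(traj, bin_width = 5, c_ref = 2, area_per_lipid = 65,
                   burn_in = 0.25, temperature = 300, cap = 10) {
  stopifnot(inherits(traj, "corral_trajectories"))
  geom <- traj$geometry
  nf <- length(traj$times)
  use <- seq.int(max(1, floor(nf * burn_in) + 1), nf)
  edges <- seq(geom$box_x_lo, geom$box_x_hi, by = bin_width)
  if (edges[length(edges)] < geom$box_x_hi)
    edges <- c(edges, geom$box_x_hi)
  centres <- (edges[-1] + edges[-length(edges)]) / 2
  counts <- numeric(length(centres))
  pool_half <- c(0, 0)
  mid <- use[ceiling(length(use) / 2)]
  for (run in traj$replicas) {
    xs <- run$x[use, , drop = FALSE]
    counts <- counts + tabulate(findInterval(pmin(pmax(as.numeric(xs),
      geom$box_x_lo), geom$box_x_hi - 1e-9), edges), length(centres))
    pool_half[1] <- pool_half[1] +
      sum(run$x[use[use <= mid], , drop = FALSE] < geom$corral_boundary_x)
    pool_half[2] <- pool_half[2] +
      sum(run$x[use[use > mid], , drop = FALSE] < geom$corral_boundary_x)
  }
  if (sum(counts) == 0) stop("no samples in any bin")
  n_frames <- length(use) * length(traj$replicas)
  widths <- diff(edges)
  conc <- 100 * (counts / n_frames) * area_per_lipid /
    (widths * (geom$box_y_hi - geom$box_y_lo))
  kT <- .kB * temperature
  w <- ifelse(conc > 0, -kT * log(conc / c_ref), cap)
  w <- pmin(w, cap)
  out <- data.frame(x = centres, concentration = conc, w = w,
                    empty = conc == 0)
  nh <- c(sum(use <= mid), sum(use > mid)) * length(traj$replicas)
  attr(out, "stationary") <-
    abs(pool_half[1] / nh[1] - pool_half[2] / nh[2]) <
    3 * sqrt(max(pool_half[1], 1)) / nh[1] + 0.05 * max(pool_half / nh)
  out
}

#' Diffusion constant from the in-plane mean-squared displacement
#'
#' Fits `MSD(t) = 4 D t` over the requested lag window using all frame
#' origins, particles, and replicas of a free-diffusion trajectory.
#'
#' @param traj A `corral_trajectories` (or single [ld_run()] result).
#' @param window Length-2 lag window in ps; must extend beyond `10 /
#'   friction` where the motion is diffusive.
#' @param friction ps^-1 (default taken from the trajectory parameters).
#' @return D in cm^2/s; attribute `msd` holds the lag/MSD table.
#' @export
msd_diffusion <- function(traj, window, friction = NULL) {
  runs <- if (inherits(traj, "corral_trajectories")) traj$replicas
          else list(traj)
  if (is.null(friction) && inherits(traj, "corral_trajectories"))
    friction <- traj$params$friction
  if (!is.null(friction) && friction > 0 && window[2] < 10 / friction)
    stop("lag window must extend past 10/friction for diffusive motion")
  times <- runs[[1]]$times
  dtf <- times[2] - times[1]
  lags <- which(times >= window[1] & times <= window[2] & times > 0)
  if (length(lags) < 2) stop("lag window contains fewer than 2 lags")
  msd <- numeric(length(lags))
  for (il in seq_along(lags)) {
    lag <- lags[il] - 1  # frame offset (frame 1 is t = 0)
    acc <- 0; cnt <- 0
    for (run in runs) {
      nf <- nrow(run$x)
      o <- seq_len(nf - lag)
      dx <- run$x[o + lag, , drop = FALSE] - run$x[o, , drop = FALSE]
      dy <- run$y[o + lag, , drop = FALSE] - run$y[o, , drop = FALSE]
      acc <- acc + sum(dx^2 + dy^2)
      cnt <- cnt + length(dx)
    }
    msd[il] <- acc / cnt
  }
  lag_t <- (lags - 1) * dtf
  slope <- coef(stats::lm(msd ~ lag_t))[[2]]
  d <- slope / 4 * 1e-4  # A^2/ps -> cm^2/s
  attr(d, "msd") <- data.frame(lag = lag_t, msd = msd)
  d
}

#' Charged-residue burial histogram
#'
#' Buries the filament to `z_min` (membrane frame) and counts charged
#' residues whose representative atom lies inside the hydrophobic region
#' (below `hydrophobic_boundary`), in 1 A bins along Z.
#'
#' @param coords Filament data frame with `z` and `resid` labels (and
#'   optionally `elety`; the representative atom of a residue is its CA if
#'   present, otherwise its first atom).
#' @param z_min Burial depth applied via [bury_filament()]; `NULL` keeps
#'   the coordinates as given.
#' @param hydrophobic_boundary Z of the headgroup/acyl-chain boundary, A
#'   (default -5: the phosphate plane minus a 5 A headgroup allowance).
#' @param charged Residue names counted as charged.
#' @param bin_width A (default 1).
#' @return Data frame with `z_lo`, `z_hi`, `count`; attribute `total`.
#' @export
burial_histogram <- function(coords, z_min = NULL,
                             hydrophobic_boundary = -5,
                             charged = c("ASP", "GLU", "LYS", "ARG"),
                             bin_width = 1) {
  if (is.null(coords$resid)) stop("residue labels are required")
  if (!is.null(z_min)) coords <- bury_filament(coords, z_min)
  if (!is.null(coords$resno)) {
    reps <- do.call(rbind, lapply(split(coords, coords$resno), function(d) {
      i <- if (!is.null(d$elety)) match("CA", d$elety) else NA
      if (is.na(i)) i <- 1
      d[i, , drop = FALSE]
    }))
  } else reps <- coords
  zc <- reps$z[reps$resid %in% charged]
  zin <- zc[zc < hydrophobic_boundary]
  lo_edge <- if (length(zin) > 0)
    floor((min(zin) - hydrophobic_boundary) / bin_width) else -1
  edges <- hydrophobic_boundary + seq(lo_edge, 0) * bin_width
  counts <- if (length(zin) > 0)
    tabulate(findInterval(zin, edges), length(edges) - 1)
  else integer(length(edges) - 1)
  out <- data.frame(z_lo = edges[-length(edges)], z_hi = edges[-1],
                    count = counts)
  attr(out, "total") <- sum(counts)
  out
}
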