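#' Parameters of the Ornstein-Uhlenbeck state-transition model
#'
#' The proteome state X_t (PC1 of the protein abundance matrix) is
#' modelled as the mean-reverting diffusion
#' `dX_t = theta * (mu - X_t) dt + sqrt(2 / beta) dB_t`:
#' `theta` (1/month) sets the timescale of transition toward the
#' attractor `mu` (the "state of ALS" on the PC1 axis) and `beta_inv`
#' (= 1/beta) scales the stochastic fluctuation -- the proteome entropy
#' rate. The stationary variance is `beta_inv / theta` and the lag-d
#' autocorrelation `exp(-theta * d)`. Fast progressors are characterised
#' by larger `theta` and larger `beta_inv` than slow progressors.
#'
#' @param theta Rate constant (> 0), 1/month.
#' @param mu Attractor state, PC1 units.
#' @param beta_inv Fluctuation variance scale (> 0).
#' @param x0 Initial state (optional; required by [simulate_ou()]).
#' @return List of class `ou_params`.
#' @export
ou_params <- function(theta, mu, beta_inv, x0 = NULL) {
  if (!is.finite(theta) || theta <= 0) stop("theta must be > 0", call. = FALSE)
  if (!is.finite(beta_inv) || beta_inv <= 0) {
    stop("beta_inv must be > 0", call. = FALSE)
  }
  structure(list(theta = theta, mu = mu, beta_inv = beta_inv, x0 = x0),
    class = "ou_params"
  )
}

# exact transition moments over a gap dt
ou_transition <- function(params, x, dt) {
  e <- exp(-params$theta * dt)
  list(
    mean = params$mu + (x - params$mu) * e,
    var = params$beta_inv / params$theta * (1 - e^2)
  )
}

#' Simulate OU sample paths by exact transition sampling
#'
#' Draws `n_paths` realizations on the time grid using the exact
#' Gaussian transition law
#' `X_{t+d} ~ N(mu + (X_t - mu) e^{-theta d}, (beta_inv/theta)(1 - e^{-2 theta d}))`,
#' so there is no discretization bias at any grid spacing. Increments
#' are independent across steps and paths.
#'
#' @param params An [ou_params()] with `x0` set (all paths start there).
#' @param t_grid Increasing time grid (months); paths start at
#'   `t_grid[1]`.
#' @param n_paths Number of paths (>= 1).
#' @param seed Optional integer seed.
#' @return List of class `ou_paths`: `times` and `states`
#'   (`n_paths` x `length(t_grid)` matrix).
#' @export
simulate_ou <- function(params, t_grid, n_paths, seed = NULL) {
  stopifnot(inherits(params, "ou_params"))
  if (is.null(params$x0)) stop("params$x0 required for simulation", call. = FALSE)
  if (is.unsorted(t_grid, strictly = TRUE)) {
    stop("t_grid must be strictly increasing", call. = FALSE)
  }
  if (n_paths < 1) stop("n_paths must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  nt <- length(t_grid)
  states <- matrix(NA_real_, nrow = n_paths, ncol = nt)
  states[, 1] <- params$x0
  for (j in seq_len(nt - 1)) {
    tr <- ou_transition(params, states[, j], t_grid[j + 1] - t_grid[j])
    states[, j + 1] <- stats::rnorm(n_paths, tr$mean, sqrt(tr$var))
  }
  structure(list(times = t_grid, states = states), class = "ou_paths")
}

#' Log-likelihood of an observed trajectory under OU parameters
#'
#' Sums the exact Gaussian transition log-densities over consecutive
#' observation pairs. By default the likelihood conditions on the first
#' observation (the first CSF draw is not the start of the process);
#' with `condition_first = FALSE` the stationary density
#' `N(mu, beta_inv/theta)` of the first point is added.
#'
#' @param params An [ou_params()].
#' @param times Strictly increasing observation times (months).
#' @param states Observed states aligned with `times`.
#' @param condition_first Condition on the first point (default TRUE).
#' @return Log-likelihood (scalar).
#' @export
ou_loglik <- function(params, times, states, condition_first = TRUE) {
  if (length(times) < 2) stop("need at least 2 time points", call. = FALSE)
  if (anyDuplicated(times)) stop("duplicate observation times", call. = FALSE)
  ord <- order(times)
  times <- times[ord]
  states <- states[ord]
  dt <- diff(times)
  tr <- ou_transition(params, states[-length(states)], dt)
  ll <- sum(stats::dnorm(states[-1], tr$mean, sqrt(tr$var), log = TRUE))
  if (!condition_first) {
    ll <- ll + stats::dnorm(states[1], params$mu,
      sqrt(params$beta_inv / params$theta),
      log = TRUE
    )
  }
  ll
}

#' Build a trajectory set
#'
#' One scalar state per (patient, time): the long-format container used
#' by the OU fitting and variance statistics.
#'
#' @param patient_id,time,state,group Aligned vectors (time in months,
#'   strictly increasing within patient; group `FP`/`SP`).
#' @return Data frame of class `trajectory_set`.
#' @export
trajectory_set <- function(patient_id, time, state, group) {
  out <- data.frame(
    patient_id = as.character(patient_id), time = time, state = state,
    group = as.character(group), stringsAsFactors = FALSE
  )
  out <- out[order(out$patient_id, out$time), ]
  for (pid in unique(out$patient_id)) {
    tt <- out$time[out$patient_id == pid]
    if (anyDuplicated(tt)) {
      stop("duplicate times for patient ", pid, call. = FALSE)
    }
  }
  rownames(out) <- NULL
  class(out) <- c("trajectory_set", "data.frame")
  out
}

#' PC1 proteome-state trajectories
#'
#' Projects samples onto the first principal component of the
#' protein-by-sample matrix (samples as observations, proteins centred);
#' missing entries are imputed to the protein mean first (flagged via the
#' `imputed` attribute). The PC1 sign is fixed so the fast-progressor
#' group mean is at least the slow-progressor mean, giving a stable
#' orientation of the proteome-state axis. Samples are grouped into
#' per-patient trajectories over months from baseline.
#'
#' @param matrix An [abundance_matrix()].
#' @param metadata Sample metadata with `alsfrsr_slope` (or `group`).
#' @return A [trajectory_set()] with attributes `imputed` and
#'   `explained_variance` (PC1 share).
#' @export
pc1_trajectories <- function(matrix, metadata) {
  matrix <- as_abundance(matrix)
  vals <- matrix$values
  if (ncol(vals) < 2) stop("need at least 2 samples", call. = FALSE)
  imputed <- anyNA(vals)
  if (imputed) {
    rm <- rowMeans(vals, na.rm = TRUE)
    idx <- which(is.na(vals), arr.ind = TRUE)
    vals[idx] <- rm[idx[, 1]]
  }
  pca <- stats::prcomp(t(vals), center = TRUE, scale. = FALSE)
  pc1 <- pca$x[, 1]
  m <- metadata[match(colnames(vals), metadata$sample_id), ]
  group <- if ("group" %in% names(m)) {
    m$group
  } else {
    ifelse(progression_label(m$alsfrsr_slope) == "fast", "FP", "SP")
  }
  if (all(c("FP", "SP") %in% group) &&
    mean(pc1[group == "FP"]) < mean(pc1[group == "SP"])) {
    pc1 <- -pc1
  }
  out <- trajectory_set(m$patient_id, m$months_from_baseline, pc1, group)
  attr(out, "imputed") <- imputed
  attr(out, "explained_variance") <-
    pca$sdev[1]^2 / sum(pca$sdev^2)
  out
}

# negative log-likelihood over all patients of one group, conditioned on
# each patient's first observation; par = (log theta, mu, log beta_inv)
ou_group_nll <- function(par, traj_list) {
  params <- ou_params(exp(par[1]), par[2], exp(par[3]))
  -sum(vapply(traj_list, function(tr) {
    ou_loglik(params, tr$time, tr$state, condition_first = TRUE)
  }, numeric(1)))
}

fit_ou_group <- function(traj_list) {
  states <- unlist(lapply(traj_list, `[[`, "state"))
  incs <- unlist(lapply(traj_list, function(tr) diff(tr$state)))
  dts <- unlist(lapply(traj_list, function(tr) diff(tr$time)))
  mu0 <- mean(states)
  beta0 <- max(1e-6, 0.5 * mean(incs^2 / dts))
  # crude rate from the lag correlation of consecutive observations
  x1 <- unlist(lapply(traj_list, function(tr) utils::head(tr$state, -1)))
  x2 <- unlist(lapply(traj_list, function(tr) tr$state[-1]))
  rho <- if (length(x1) > 2 && stats::sd(x1) > 0 && stats::sd(x2) > 0) {
    stats::cor(x1, x2)
  } else {
    0.5
  }
  rho <- min(0.95, max(0.05, rho))
  theta0 <- -log(rho) / mean(dts)
  par0 <- c(log(theta0), mu0, log(beta0))
  opt <- stats::optim(par0, ou_group_nll,
    traj_list = traj_list,
    method = "Nelder-Mead",
    control = list(maxit = 2000, reltol = 1e-10)
  )
  opt2 <- tryCatch(
    stats::optim(opt$par, ou_group_nll,
      traj_list = traj_list,
      method = "BFGS", control = list(maxit = 200)
    ),
    error = function(e) opt
  )
  if (opt2$value <= opt$value) opt <- opt2
  params <- ou_params(exp(opt$par[1]), opt$par[2], exp(opt$par[3]))
  params$x0 <- mean(vapply(traj_list, function(tr) tr$state[1], numeric(1)))
  list(params = params, converged = opt$convergence == 0,
    loglik = -opt$value
  )
}

#' Fit OU parameters per progression group
#'
#' Joint maximum-likelihood estimation of `(theta, mu, beta_inv)` shared
#' by all patients of a group: each patient contributes exact transition
#' densities conditioned on their first observation, and positivity of
#' `theta` and `beta_inv` is enforced by optimizing on the log scale.
#' Each group's `x0` is reported as the mean first observation.
#'
#' @param trajectories A [trajectory_set()] (e.g. from
#'   [pc1_trajectories()]); patients with a single visit are dropped with
#'   a warning.
#' @return Named list (one element per group) of lists with `params`
#'   ([ou_params()]), `converged`, `loglik`.
#' @export
fit_ou <- function(trajectories) {
  split_pat <- split(
    as.data.frame(trajectories),
    trajectories$patient_id
  )
  usable <- vapply(split_pat, nrow, 0L) >= 2
  if (any(!usable)) {
    warning("dropping single-visit patient(s): ",
      paste(names(split_pat)[!usable], collapse = ", "),
      call. = FALSE
    )
    split_pat <- split_pat[usable]
  }
  groups <- vapply(split_pat, function(tr) tr$group[1], "")
  out <- lapply(unique(groups), function(g) {
    members <- split_pat[groups == g]
    if (length(members) < 2) {
      stop("need at least 2 usable patients in group ", g, call. = FALSE)
    }
    fit_ou_group(members)
  })
  names(out) <- unique(groups)
  out
}

#' Backcast the proteome state to pre-symptomatic time
#'
#' Simulates the OU process backwards in time from a pre-symptomatic
#' reference state (`x = 0` by convention) at `-t_back_months` to the
#' observed state at time 0. In the default `"bridge"` mode paths are
#' drawn from the exact OU diffusion bridge: at each grid step the next
#' state is sampled from its Gaussian law conditioned on both the
#' current state and the fixed endpoint, so every path ends exactly at
#' `x_at_zero`. Mode `"forward"` drops the endpoint conditioning and
#' simply runs the process forward from the reference state.
#'
#' @param params An [ou_params()].
#' @param x_at_zero Observed state at time 0 (e.g. the baseline PC1).
#' @param t_back_months Months before first draw to start from (> 0).
#' @param n_paths Number of paths.
#' @param seed Optional integer seed.
#' @param mode `"bridge"` (default) or `"forward"`.
#' @param n_steps Grid resolution (default 60 intervals).
#' @return An `ou_paths` list with negative `times` ending at 0.
#' @export
backcast <- function(params, x_at_zero, t_back_months, n_paths,
                     seed = NULL, mode = c("bridge", "forward"),
                     n_steps = 60) {
  stopifnot(inherits(params, "ou_params"))
  mode <- match.arg(mode)
  if (t_back_months <= 0) stop("t_back_months must be > 0", call. = FALSE)
  t_grid <- seq(-t_back_months, 0, length.out = n_steps + 1)
  start <- ou_params(params$theta, params$mu, params$beta_inv, x0 = 0)
  if (mode == "forward") {
    return(simulate_ou(start, t_grid, n_paths, seed = seed))
  }
  if (!is.null(seed)) set.seed(seed)
  nt <- length(t_grid)
  states <- matrix(NA_real_, nrow = n_paths, ncol = nt)
  states[, 1] <- 0
  states[, nt] <- x_at_zero
  for (j in seq_len(nt - 2)) {
    d1 <- t_grid[j + 1] - t_grid[j]
    d2 <- t_grid[nt] - t_grid[j + 1]
    tr1 <- ou_transition(params, states[, j], d1)
    e2 <- exp(-params$theta * d2)
    v2 <- params$beta_inv / params$theta * (1 - e2^2)
    # combine forward transition with endpoint likelihood (both Gaussian)
    prec <- 1 / tr1$var + e2^2 / v2
    mean_post <- (tr1$mean / tr1$var +
      e2 * (x_at_zero - params$mu) / v2 + e2^2 * params$mu / v2) / prec
    states[, j + 1] <- stats::rnorm(n_paths, mean_post, sqrt(1 / prec))
  }
  structure(list(times = t_grid, states = states), class = "ou_paths")
}

#' Restrict simulated paths to visit times
#'
#' Subsets each path to the requested visit times without re-simulation;
#' times off the grid are filled by linear interpolation within each
#' path. Used to make model simulations comparable to sparsely sampled
#' clinical data.
#'
#' @param paths An `ou_paths` object.
#' @param visit_times Times to keep (within the simulated range).
#' @return An `ou_paths` object on `visit_times`.
#' @export
downsample_paths <- function(paths, visit_times) {
  visit_times <- sort(visit_times)
  if (min(visit_times) < min(paths$times) - 1e-9 ||
    max(visit_times) > max(paths$times) + 1e-9) {
    stop("visit_times outside the simulated range", call. = FALSE)
  }
  hit <- match(round(visit_times, 9), round(paths$times, 9))
  if (!anyNA(hit)) {
    states <- paths$states[, hit, drop = FALSE]
  } else {
    states <- t(apply(paths$states, 1, function(path) {
      stats::approx(paths$times, path, xout = visit_times)$y
    }))
  }
  structure(list(times = visit_times, states = states), class = "ou_paths")
}

#' Proteome-variance statistic per progression group
#'
#' For each patient, the mean squared PC1 increment per month
#' (`mean((dX)^2 / dt)` over successive visits) -- an estimate of the
#' local fluctuation rate `2 * beta_inv` of the state process. Group
#' statistics are medians across patients; the FP/SP ratio summarizes
#' the variance contrast between fast and slow progressors.
#'
#' @param trajectories A [trajectory_set()].
#' @return List with `per_patient` (data frame), `group_stats` (named
#'   medians), and `ratio` (FP over SP; `NA` if either group absent).
#' @export
variance_biomarker <- function(trajectories) {
  split_pat <- split(as.data.frame(trajectories), trajectories$patient_id)
  usable <- vapply(split_pat, nrow, 0L) >= 2
  if (any(!usable)) {
    warning("excluding single-visit patient(s): ",
      paste(names(split_pat)[!usable], collapse = ", "),
      call. = FALSE
    )
    split_pat <- split_pat[usable]
  }
  per_patient <- do.call(rbind, lapply(split_pat, function(tr) {
    tr <- tr[order(tr$time), ]
    data.frame(
      patient_id = tr$patient_id[1],
      group = tr$group[1],
      variance_rate = mean(diff(tr$state)^2 / diff(tr$time)),
      n_visits = nrow(tr),
      stringsAsFactors = FALSE
    )
  }))
  rownames(per_patient) <- NULL
  group_stats <- tapply(per_patient$variance_rate, per_patient$group,
    stats::median
  )
  ratio <- if (all(c("FP", "SP") %in% names(group_stats))) {
    unname(group_stats["FP"] / group_stats["SP"])
  } else {
    NA_real_
  }
  list(
    per_patient = per_patient,
    group_stats = group_stats,
    ratio = ratio
  )
}
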