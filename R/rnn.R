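## Task-trained recurrent network for flexible manual interception:
## rectified-tanh rate units, Euler integration, BPTT/Adam training (compiled
## core), node classification and geometry, perturbation and connectivity
## analyses, and latent-dynamics comparison.

#' Recurrent-network hyperparameters
#'
#' @param n_units hidden units.
#' @param tau membrane time constant, ms.
#' @param g recurrent initialization scale.
#' @param alpha activity penalty weight on the squared rates summed over time.
#' @param lr Adam learning rate.
#' @param dt Euler integration step, ms (must satisfy `dt <= tau / 2`).
#' @param sparsity nonzero fraction of the initial recurrent matrix for the
#'   sparse variant.
#' @param j_init_scale `"sqrtN"` for sd = g/sqrt(N) (the standard scaling) or
#'   `"N"` for sd = g/N.
#' @param b_init_sd sd of the input-weight initialization, default the
#'   standard 1/sqrt(n_inputs) scaling. A strictly zero B (with zero readout
#'   and zero initial state) is an exact fixed point of the rectified-tanh
#'   dynamics with identically zero gradients, so B must start random for
#'   training to be possible.
#' @return Object of class `rnn_params`.
#' @export
rnn_params <- function(n_units = 200, tau = 50, g = 1.5, alpha = 1e-7,
                       lr = 0.001, dt = 10, sparsity = 0.1,
                       j_init_scale = c("sqrtN", "N"),
                       b_init_sd = 1 / sqrt(5)) {
  stopifnot(n_units >= 1, dt <= tau / 2, b_init_sd > 0)
  structure(list(n_units = n_units, tau = tau, g = g, alpha = alpha,
                 lr = lr, dt = dt, sparsity = sparsity,
                 j_init_scale = match.arg(j_init_scale),
                 b_init_sd = b_init_sd), class = "rnn_params")
}

RNN_T_MAX <- 150L          # padded trial length in bins (1500 ms at dt = 10)
RNN_RT_RANGE <- c(150, 250)  # reaction time, ms from GO to movement onset
RNN_MT_RANGE <- c(250, 400)  # movement time, ms from movement onset to touch

#' Build one network trial
#'
#' Assembles the 5-channel input (intention x/y present only in
#' \[MO-50, MO\], target x/y throughout, GO step) and the target output
#' (minimum-jerk hand velocity towards the interception point, nonzero only
#' during the movement) on the padded trial grid. The intention and the
#' desired reach aim at the interception point: where the target will be at
#' touch. After the touch the target holds its position and the desired
#' output is zero.
#'
#' @param target_velocity deg/s.
#' @param theta0 target angle at onset, degrees.
#' @param delay GO delay in ms (task range 400-800).
#' @param rt reaction time, ms from GO to movement onset.
#' @param mt movement time, ms from movement onset to touch.
#' @param params an [rnn_params()].
#' @return List with `inputs` (5 x T), `target_output` (2 x T, a.u./s),
#'   `ip` (interception point), event bins and the condition labels.
#' @export
build_rnn_trial <- function(target_velocity, theta0, delay, rt = 200,
                            mt = 300, params = rnn_params()) {
  dt <- params$dt
  tt <- (seq_len(RNN_T_MAX) - 1) * dt
  go <- delay; mo <- go + rt; touch <- mo + mt
  stopifnot(touch <= max(tt) + dt)
  ang <- theta0 + target_velocity * pmin(tt, touch) / 1000
  ip_ang <- (theta0 + target_velocity * touch / 1000) %% 360
  ip <- TARGET_RADIUS * c(cosd(ip_ang), sind(ip_ang))
  U <- matrix(0, 5, RNN_T_MAX)
  U[3, ] <- TARGET_RADIUS * cosd(ang)
  U[4, ] <- TARGET_RADIUS * sind(ang)
  U[5, ] <- as.numeric(tt >= go)
  U[1:2, tt >= mo - 50 & tt <= mo] <- ip
  Z <- matrix(0, 2, RNN_T_MAX)
  mv <- tt >= mo & tt < touch
  s <- (tt[mv] - mo) / mt
  prof <- (30 * s^2 - 60 * s^3 + 30 * s^4) / (mt / 1000)
  Z[1, mv] <- ip[1] * prof
  Z[2, mv] <- ip[2] * prof
  list(inputs = U, target_output = Z, ip = ip,
       target_velocity = target_velocity, theta0 = theta0 %% 360,
       endpoint_angle = ip_ang, sector = assign_sector(ip_ang),
       go_bin = which(tt >= go)[1], mo_bin = which(tt >= mo)[1],
       touch_bin = which(tt >= touch)[1])
}

## Stack a list of trials into the input/target cubes the compiled core uses.
stack_rnn_trials <- function(trials) {
  K <- length(trials)
  U <- array(0, c(5, RNN_T_MAX, K))
  Z <- array(0, c(2, RNN_T_MAX, K))
  for (k in seq_len(K)) {
    U[, , k] <- trials[[k]]$inputs
    Z[, , k] <- trials[[k]]$target_output
  }
  list(U = U, Z = Z)
}

#' Random pool of network trials
#'
#' @param n number of trials.
#' @param params an [rnn_params()].
#' @param velocities candidate target velocities, deg/s.
#' @param seed integer RNG seed.
#' @return List of trials from [build_rnn_trial()].
#' @export
rnn_trial_pool <- function(n, params = rnn_params(),
                           velocities = TASK_VELOCITIES, seed = 1L) {
  set.seed(seed)
  lapply(seq_len(n), function(i)
    build_rnn_trial(sample(velocities, 1), runif(1, 0, 360),
                    runif(1, 400, 800), runif(1, RNN_RT_RANGE[1], RNN_RT_RANGE[2]),
                    runif(1, RNN_MT_RANGE[1], RNN_MT_RANGE[2]), params))
}

#' Fixed validation set
#'
#' A reproducible set of interception trials shared by all models and
#' perturbation experiments.
#'
#' @param n trials (500 in the standard protocol).
#' @param params an [rnn_params()].
#' @param seed integer RNG seed of the shared set.
#' @return List of trials.
#' @export
rnn_validation_set <- function(n = 500, params = rnn_params(), seed = 1000L) {
  rnn_trial_pool(n, params, seed = seed)
}

## Zero the input channels a variant does not receive.
variant_input_mask <- function(variant) {
  switch(variant,
    main = , sparse = rep(TRUE, 5),
    GM = c(TRUE, TRUE, FALSE, FALSE, TRUE),   # intention + GO only
    GT = c(FALSE, FALSE, TRUE, TRUE, TRUE),   # target + GO only
    stop("unknown variant: ", variant))
}

#' Train an interception network
#'
#' Initializes the recurrent weights J ~ Normal(0, sd) (sd = g/sqrt(N) or
#' g/N per `j_init_scale`), the input weights B ~ Normal(0, 1/sqrt(5)) and
#' the readout W = 0, then minimizes the mean squared output error plus the
#' activity penalty `alpha * sum_t sum_n r^2` with Adam (batched BPTT,
#' gradient-norm clipping at 1) over random mini-batches from a fixed trial
#' pool.
#'
#' @param params an [rnn_params()].
#' @param n_steps optimizer steps.
#' @param batch_size trials per step.
#' @param pool_size size of the random trial pool batches are drawn from.
#' @param variant `"main"`, `"GM"` (no target input), `"GT"` (no intention
#'   input) or `"sparse"` (10 percent nonzero initial J).
#' @param seed integer RNG seed (weights, pool, batch order).
#' @return Object of class `trained_rnn`: weights `J`, `B`, `W`, the
#'   training `loss` log, `params`, `variant`, `seed`.
#' @export
train_rnn <- function(params = rnn_params(), n_steps = 1500, batch_size = 32,
                      pool_size = 640, variant = "main", seed = 1L) {
  mask <- variant_input_mask(variant)
  set.seed(seed)
  N <- params$n_units
  sdJ <- if (params$j_init_scale == "sqrtN") params$g / sqrt(N) else params$g / N
  J <- matrix(rnorm(N * N, 0, sdJ), N, N)
  if (variant == "sparse")
    J <- J * matrix(runif(N * N) < params$sparsity, N, N) / sqrt(params$sparsity)
  B <- matrix(rnorm(N * 5, 0, params$b_init_sd), N, 5)
  W <- matrix(0, 2, N)
  pool <- rnn_trial_pool(pool_size, params, seed = seed + 1L)
  st <- stack_rnn_trials(pool)
  if (!all(mask)) st$U[!mask, , ] <- 0
  batch_idx <- matrix(sample.int(pool_size, n_steps * batch_size,
                                 replace = TRUE), n_steps, batch_size)
  fit <- rnn_train_cpp(J, B, W, st$U, st$Z, batch_idx,
                       params$dt, params$tau, params$alpha, params$lr,
                       clip = 1)
  structure(list(J = fit$J, B = fit$B, W = fit$W,
                 loss = as.numeric(fit$loss), mse = as.numeric(fit$mse),
                 params = params, variant = variant, seed = seed,
                 input_mask = mask),
            class = "trained_rnn")
}

#' @export
print.trained_rnn <- function(x, ...) {
  cat(sprintf("Trained interception RNN (%s): %d units, %d training steps\n",
              x$variant, x$params$n_units, length(x$loss)))
  cat(sprintf("  final loss %.3g (from %.3g)\n",
              mean(utils::tail(x$loss, 20)), x$loss[1]))
  invisible(x)
}

#' Simulate a network on a set of trials
#'
#' @param model a [train_rnn()] model.
#' @param trials list of trials from [build_rnn_trial()].
#' @return List with `rates` (units x T x trials) and `outputs`
#'   (2 x T x trials).
#' @export
rnn_simulate <- function(model, trials) {
  st <- stack_rnn_trials(trials)
  if (!all(model$input_mask)) st$U[!model$input_mask, , ] <- 0
  rnn_forward_cpp(model$J, model$B, model$W, st$U,
                  model$params$dt, model$params$tau)
}

#' Validate reach endpoints on a trial set
#'
#' Simulates each trial, integrates the output velocity from movement onset
#' to touch, and measures the distance from the endpoint to the target's
#' touch-time position (the interception point).
#'
#' @param model a [train_rnn()] model.
#' @param trials validation trials (default the shared fixed set of 500).
#' @return List with `mean`, `sd` and the per-trial `distances` (a.u.).
#' @export
validate_rnn <- function(model, trials = rnn_validation_set(params = model$params)) {
  sim <- rnn_simulate(model, trials)
  dt_s <- model$params$dt / 1000
  d <- vapply(seq_along(trials), function(k) {
    tr <- trials[[k]]
    span <- tr$mo_bin:(tr$touch_bin - 1L)
    endpoint <- rowSums(sim$outputs[, span, k, drop = FALSE][, , 1]) * dt_s
    sqrt(sum((endpoint - tr$ip)^2))
  }, 1)
  list(mean = mean(d), sd = sd(d), distances = d)
}

#' Node activity over the condition grid as a population recording
#'
#' Builds interception trials covering the 5 x 8 condition grid (endpoint
#' angles jittered within sector, delays uniform in the task range),
#' simulates the network and aligns node rates to each trial's movement
#' onset.
#'
#' @param model a [train_rnn()] model.
#' @param trials_per_cell trials per (velocity, sector) cell.
#' @param window window around movement onset to keep, ms.
#' @param seed integer RNG seed.
#' @return A [population_activity()] of node rates (unitless, in \[0, 1)).
#' @export
rnn_condition_activity <- function(model, trials_per_cell = 5,
                                   window = c(-100, 100), seed = 1L) {
  params <- model$params
  set.seed(seed)
  grid <- condition_grid()
  rows <- grid[rep(seq_len(nrow(grid)), each = trials_per_cell), ]
  n <- nrow(rows)
  endpoint <- (rows$sector_center +
                 runif(n, -SECTOR_WIDTH / 2, SECTOR_WIDTH / 2)) %% 360
  delay <- runif(n, 400, 800)
  rt <- runif(n, RNN_RT_RANGE[1], RNN_RT_RANGE[2])
  mt <- runif(n, RNN_MT_RANGE[1], RNN_MT_RANGE[2])
  touch <- delay + rt + mt
  theta0 <- (endpoint - rows$target_velocity * touch / 1000) %% 360
  trials <- lapply(seq_len(n), function(i)
    build_rnn_trial(rows$target_velocity[i], theta0[i], delay[i], rt[i],
                    mt[i], params))
  sim <- rnn_simulate(model, trials)
  dt <- params$dt
  off <- seq(floor(window[1] / dt), ceiling(window[2] / dt))
  rates <- array(0, c(params$n_units, n, length(off)))
  for (k in seq_len(n)) {
    bins <- trials[[k]]$mo_bin + off
    rates[, k, ] <- sim$rates[, bins, k]
  }
  tt <- data.frame(
    trial = seq_len(n), target_velocity = rows$target_velocity,
    initial_target_angle = theta0, reach_endpoint_angle = endpoint,
    sector = assign_sector(endpoint), t_target_on = 0, t_go = delay,
    t_move_onset = delay + rt, t_touch = touch,
    row.names = NULL)
  class(tt) <- c("trial_table", "data.frame")
  population_activity(rates, tt, bin_width = dt, alignment = "MO",
                      bin_centers = off * dt)
}

#' Classify the modulation type of every active node
#'
#' Applies the single-neuron classification criteria to the node rates in
#' the peri-movement window. Nodes whose temporal mean rate over the
#' condition grid is below `active_threshold` are excluded as inactive.
#'
#' @param model a [train_rnn()] model.
#' @param activity optional precomputed [rnn_condition_activity()].
#' @param trials_per_cell,seed forwarded to [rnn_condition_activity()].
#' @param active_threshold minimum temporal-mean rate for an active node.
#' @param alpha significance level per test.
#' @return List with `labels` (per active node [classify_modulation()]
#'   results), `active` (indices), `fractions` (gain / pd_shift / addition /
#'   none, as fractions of active nodes).
#' @export
classify_nodes <- function(model, activity = NULL, trials_per_cell = 5,
                           active_threshold = 0.01, alpha = 0.05, seed = 1L) {
  if (is.null(activity))
    activity <- rnn_condition_activity(model, trials_per_cell, seed = seed)
  mean_rate <- apply(activity$rates, 1, mean)
  active <- which(mean_rate > active_threshold)
  X <- window_rates(activity, c(-100, 100))
  labels <- lapply(active, function(j)
    classify_modulation_rates(X[, j], activity$trial_table,
                              alpha = alpha, seed = seed))
  frac <- function(f) mean(vapply(labels, function(l) isTRUE(l[[f]]), TRUE))
  list(labels = labels, active = active,
       n_active = length(active),
       fractions = c(gain = frac("gain"), pd_shift = frac("pd_shift"),
                     addition = frac("addition"), none = frac("none")))
}

#' Orbital geometry of the node population
#'
#' Runs the neural-state pipeline (window average, z-score, PCA, ellipse
#' fits, tilt metrics) on the network's node activity at movement onset.
#'
#' @param model a [train_rnn()] model.
#' @param activity optional precomputed [rnn_condition_activity()].
#' @param trials_per_cell,seed forwarded to [rnn_condition_activity()].
#' @param window state window around movement onset, ms.
#' @return A [geometry_summary()].
#' @export
node_geometry <- function(model, activity = NULL, trials_per_cell = 5,
                          window = c(-50, 50), seed = 1L) {
  if (is.null(activity))
    activity <- rnn_condition_activity(model, trials_per_cell, seed = seed)
  geometry_summary(suppressMessages(neural_states(activity, window, n_pcs = 3)))
}

#' Ablate a subset of nodes
#'
#' Zeroes every connection touching the subset (recurrent rows and columns,
#' input rows, readout columns) for the whole trial; the original model is
#' untouched.
#'
#' @param model a [train_rnn()] model.
#' @param nodes nonempty node indices.
#' @return The perturbed `trained_rnn`.
#' @export
ablate <- function(model, nodes) {
  if (!length(nodes)) stop("node subset is empty")
  m <- model
  m$J[nodes, ] <- 0; m$J[, nodes] <- 0
  m$B[nodes, ] <- 0; m$W[, nodes] <- 0
  m
}

#' Scale connections between two modulation classes
#'
#' Multiplies the recurrent weights from `from_class` nodes to `to_class`
#' nodes by `factor`.
#'
#' @param model a [train_rnn()] model.
#' @param labels per-node class labels (character; `NA` allowed).
#' @param from_class,to_class class names present in `labels`.
#' @param factor scale factor (1.5 in the standard perturbation).
#' @return The perturbed `trained_rnn`.
#' @export
scale_connection <- function(model, labels, from_class, to_class,
                             factor = 1.5) {
  stopifnot(length(labels) == nrow(model$J))
  from <- which(labels == from_class); to <- which(labels == to_class)
  if (!length(from)) stop("unknown or empty class: ", from_class)
  if (!length(to)) stop("unknown or empty class: ", to_class)
  m <- model
  m$J[to, from] <- m$J[to, from] * factor
  m
}

#' Mean absolute connectivity between modulation classes
#'
#' @param model a [train_rnn()] model.
#' @param labels per-node class labels (character; `NA` nodes are ignored).
#' @return List with `matrix` (to x from mean |J|; `NaN` for empty classes),
#'   and `omnibus` (Kruskal-Wallis across class pairs).
#' @export
connectivity_summary <- function(model, labels) {
  stopifnot(length(labels) == nrow(model$J))
  classes <- sort(unique(na.omit(labels)))
  M <- matrix(NaN, length(classes), length(classes),
              dimnames = list(to = classes, from = classes))
  vals <- list()
  for (to in classes) for (from in classes) {
    block <- abs(model$J[which(labels == to), which(labels == from),
                         drop = FALSE])
    if (to == from && nrow(block) > 0) diag(block) <- NA  # drop self-weights
    v <- as.numeric(block); v <- v[!is.na(v)]
    if (length(v)) {
      M[to, from] <- mean(v)
      vals[[paste(from, to, sep = "->")]] <- v
    }
  }
  omnibus <- if (length(vals) >= 2)
    kruskal.test(unlist(vals),
                 factor(rep(names(vals), lengths(vals)))) else NULL
  if (!is.null(omnibus) && is.nan(omnibus$p.value)) {
    ## all weights tied across every pair: no evidence of structure
    omnibus$p.value <- 1
    omnibus$statistic[] <- 0
  }
  list(matrix = M, omnibus = omnibus)
}

#' Compare data and network latent dynamics
#'
#' Reduces both condition-binned activity matrices to their first
#' `n_pcs` principal components, computes canonical correlations between the
#' score matrices, and the symmetric Procrustes disparity after optimal
#' translation, rotation and scaling.
#'
#' @param data_mat,model_mat bins x features matrices with matching row
#'   counts (e.g. condition-averaged time bins x neurons/nodes).
#' @param n_pcs PCs retained on each side before comparison.
#' @param n_cc canonical pairs reported.
#' @return List with `canonical_r` (length `n_cc`) and `procrustes`
#'   (disparity).
#' @export
compare_latent <- function(data_mat, model_mat, n_pcs = 30, n_cc = 10) {
  data_mat <- as.matrix(data_mat); model_mat <- as.matrix(model_mat)
  if (nrow(data_mat) != nrow(model_mat))
    stop("bin-count mismatch: ", nrow(data_mat), " vs ", nrow(model_mat))
  red <- function(X) {
    p <- prcomp(X, center = TRUE, scale. = FALSE)
    p$x[, seq_len(min(n_pcs, ncol(p$x))), drop = FALSE]
  }
  Xs <- red(data_mat); Ys <- red(model_mat)
  k <- min(ncol(Xs), ncol(Ys), n_cc)
  cc <- stats::cancor(Xs, Ys)
  pr <- vegan::procrustes(Xs, Ys, symmetric = TRUE)
  list(canonical_r = cc$cor[seq_len(k)], procrustes = pr$ss)
}
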