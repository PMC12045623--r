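#' @useDynLib neurorbit, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx aov coef cor cov fitted kruskal.test lm median na.omit
#'   nls nls.control p.adjust pf prcomp predict pt quantile resid rnorm rpois
#'   runif sd setNames t.test var wilcox.test
#' @importFrom utils head read.csv write.csv
NULL

## Standard condition grid of the interception task: five signed target
## angular velocities crossed with eight 45-degree reach-direction sectors.
TASK_VELOCITIES <- c(-240, -120, 0, 120, 240)
TARGET_RADIUS <- 0.15       # a.u.; physical radius is 15 cm
SECTOR_WIDTH <- 45

#' Trial condition of the flexible manual interception task
#'
#' Bundles the labels and event times of a single interception trial: a target
#' appears on a circle of radius 15 cm (0.15 a.u.), either static or rotating
#' at a constant angular velocity; after a randomized delay the GO cue releases
#' a reach that ends at the touch of the screen.
#'
#' @param target_velocity signed angular velocity in degrees/s, counter-
#'   clockwise positive. The standard grid uses -240, -120, 0, 120, 240.
#' @param initial_target_angle target angle at target onset, degrees in
#'   \[0, 360).
#' @param reach_endpoint_angle angle of the touch endpoint, degrees.
#' @param t_target_on,t_go,t_move_onset,t_touch event times in ms from trial
#'   start (target on < GO < movement onset < touch).
#' @return An object of class `trial_condition` (a named list).
#' @examples
#' trial_condition(120, 30, 90, 0, 600, 800, 1100)
#' @export
trial_condition <- function(target_velocity, initial_target_angle,
                            reach_endpoint_angle = NA_real_,
                            t_target_on = 0, t_go = 600,
                            t_move_onset = 800, t_touch = 1100) {
  stopifnot(is.finite(target_velocity), is.finite(initial_target_angle))
  if (!(t_target_on < t_go && t_go < t_move_onset && t_move_onset < t_touch))
    stop("event times must be ordered: target on < GO < movement onset < touch")
  delay <- t_go - t_target_on
  if (delay < 400 || delay > 800)
    warning("delay (GO - target on) outside the task's 400-800 ms range")
  structure(list(
    target_velocity = target_velocity,
    initial_target_angle = initial_target_angle %% 360,
    reach_endpoint_angle = if (is.na(reach_endpoint_angle)) NA_real_
                           else reach_endpoint_angle %% 360,
    sector = if (is.na(reach_endpoint_angle)) NA_integer_
             else assign_sector(reach_endpoint_angle),
    t_target_on = t_target_on, t_go = t_go,
    t_move_onset = t_move_onset, t_touch = t_touch
  ), class = "trial_condition")
}

#' @export
print.trial_condition <- function(x, ...) {
  cat(sprintf(
    "Interception trial: vel %g deg/s, target on at %g deg, endpoint %s (sector %s)\n",
    x$target_velocity, x$initial_target_angle,
    ifelse(is.na(x$reach_endpoint_angle), "?",
           sprintf("%.1f deg", x$reach_endpoint_angle)),
    ifelse(is.na(x$sector), "?", x$sector)))
  cat(sprintf("  TO %g  GO %g  MO %g  Touch %g ms\n",
              x$t_target_on, x$t_go, x$t_move_onset, x$t_touch))
  invisible(x)
}

#' The 5 x 8 condition grid
#'
#' @return A data frame with one row per cell: `target_velocity`, `sector`,
#'   and the sector center angle in degrees.
#' @export
condition_grid <- function() {
  g <- expand.grid(target_velocity = TASK_VELOCITIES, sector = 1:8,
                   KEEP.OUT.ATTRS = FALSE)
  g$sector_center <- sector_centers()[g$sector]
  g[order(g$target_velocity, g$sector), , drop = FALSE]
}

#' Sector center angles
#'
#' Reach-direction sectors tile \[0, 360) in eight half-open 45-degree bins
#' anchored at 0 degrees; sector k covers \[(k-1)*45, k*45).
#'
#' @return Numeric vector of the 8 sector center angles (22.5, 67.5, ...).
#' @export
sector_centers <- function() (seq_len(8) - 0.5) * SECTOR_WIDTH

#' Target angle at a given time
#'
#' The target moves on a circle at constant angular velocity from its onset
#' angle, so its angle at time t is the onset angle plus velocity times the
#' elapsed time.
#'
#' @param condition a [trial_condition()].
#' @param t time in ms from trial start; must not precede target onset.
#' @return Angle in degrees in \[0, 360).
#' @export
target_angle_at <- function(condition, t) {
  stopifnot(inherits(condition, "trial_condition"))
  if (any(t < condition$t_target_on))
    stop("t precedes target onset")
  (condition$initial_target_angle +
     condition$target_velocity * (t - condition$t_target_on) / 1000) %% 360
}

#' Assign a reach-direction sector
#'
#' @param angle angle(s) in degrees (any finite value; wrapped into \[0,360)).
#' @return Integer sector label(s) in 1..8.
#' @export
assign_sector <- function(angle) {
  stopifnot(all(is.finite(angle)))
  as.integer(floor((angle %% 360) / SECTOR_WIDTH)) + 1L
}

#' Bell-shaped (minimum-jerk) speed profile
#'
#' The desired hand-speed curve of a point-to-point reach: the minimum-jerk
#' profile, a smooth unimodal curve that is zero at both ends, peaks at
#' mid-movement at 1.875 * displacement / duration, and integrates exactly to
#' the displacement.
#'
#' @param duration movement duration in ms.
#' @param displacement total path length (any length unit).
#' @param n number of equally spaced samples over \[0, duration\].
#' @return A data frame with `t` (ms) and `speed` (displacement units per s).
#' @export
bell_speed_profile <- function(duration, displacement, n = 101) {
  if (duration <= 0) stop("duration must be positive")
  tt <- seq(0, duration, length.out = n)
  s <- tt / duration
  dur_s <- duration / 1000
  speed <- displacement / dur_s * (30 * s^2 - 60 * s^3 + 30 * s^4)
  data.frame(t = tt, speed = speed)
}

#' Build a trial table for the standard task
#'
#' Draws trials over the 5 x 8 condition grid with randomized target-onset
#' angles, endpoint angles inside the assigned sector, and delays uniform in
#' 400-800 ms. Movement onset follows GO by the reaction time and the touch
#' ends the movement.
#'
#' @param trials_per_cell trials per (velocity, sector) cell.
#' @param reaction_time ms from GO to movement onset.
#' @param movement_time ms from movement onset to touch.
#' @param jitter if `TRUE`, endpoint angles are uniform within their sector;
#'   otherwise they sit at the sector centers.
#' @param seed integer RNG seed.
#' @return A data frame (one row per trial) with class `trial_table`.
#' @export
build_trial_table <- function(trials_per_cell = 15, reaction_time = 200,
                              movement_time = 300, jitter = TRUE, seed = 1L) {
  set.seed(seed)
  grid <- condition_grid()
  rows <- grid[rep(seq_len(nrow(grid)), each = trials_per_cell), ]
  n <- nrow(rows)
  off <- if (jitter) runif(n, -SECTOR_WIDTH / 2, SECTOR_WIDTH / 2) else 0
  endpoint <- (rows$sector_center + off) %% 360
  delay <- runif(n, 400, 800)
  t_go <- delay
  t_mo <- t_go + reaction_time
  t_touch <- t_mo + movement_time
  ## the endpoint is where the target is at touch, so onset angle follows
  theta0 <- (endpoint - rows$target_velocity * t_touch / 1000) %% 360
  out <- data.frame(
    trial = seq_len(n),
    target_velocity = rows$target_velocity,
    initial_target_angle = theta0,
    reach_endpoint_angle = endpoint,
    sector = rows$sector,
    t_target_on = 0, t_go = t_go, t_move_onset = t_mo, t_touch = t_touch,
    row.names = NULL)
  class(out) <- c("trial_table", "data.frame")
  out
}

#' Write / read a trial table as CSV
#'
#' @param x a trial table data frame.
#' @param path file path.
#' @return `read_trial_table` returns the trial table.
#' @export
write_trial_table <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  out <- read.csv(path)
  class(out) <- c("trial_table", "data.frame")
  out
}
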