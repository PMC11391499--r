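#' Build the seven-port hexagonal wall
#'
#' The operant wall carries seven ports: one central port at the origin and
#' six ports at the vertices of a regular hexagon around it. Ports are
#' identified by integer ids 0--6 with 0 the central port; coordinates are in
#' millimetres with x rightward and y upward.
#'
#' @param spacing Centre-to-neighbour distance in mm. Only the relative
#'   geometry matters downstream, so this is a free scale; it must exceed
#'   twice the port radius so ports do not overlap.
#' @param port_radius Port radius in mm (11 mm hardware ports).
#'
#' @return An object of class `port_wall`: a list with `ports` (data frame of
#'   `port`, `x`, `y`), `spacing`, and `port_radius`.
#' @examples
#' wall <- build_port_wall()
#' wall$ports
#' @export
build_port_wall <- function(spacing = 50, port_radius = 11) {
  if (!is.numeric(spacing) || length(spacing) != 1 || spacing <= 2 * port_radius) {
    stop("`spacing` must be a single number larger than 2 * port_radius (ports would overlap)")
  }
  ang <- seq(0, 300, by = 60) * pi / 180
  ports <- data.frame(
    port = 0:6,
    x = c(0, round(spacing * cos(ang), 12)),
    y = c(0, round(spacing * sin(ang), 12))
  )
  structure(
    list(ports = ports, spacing = spacing, port_radius = port_radius),
    class = "port_wall"
  )
}

#' @export
print.port_wall <- function(x, ...) {
  cat("<port_wall> 7 ports, spacing", x$spacing, "mm, port radius",
      x$port_radius, "mm\n")
  print(x$ports, row.names = FALSE)
  invisible(x)
}

#' Look up port coordinates
#'
#' @param wall A `port_wall`.
#' @param port Vector of port ids (0--6); unknown ids are an error.
#' @return Matrix with columns `x`, `y` (mm), one row per requested port.
#' @export
port_xy <- function(wall, port) {
  i <- match(port, wall$ports$port)
  if (anyNA(i)) stop("unknown port id: ", paste(port[is.na(i)], collapse = ", "))
  cbind(x = wall$ports$x[i], y = wall$ports$y[i])
}

#' The six movement directions of the task
#'
#' Directions are the displacement angles between adjacent ports:
#' 0, 60, 120, 180, -120 and -60 degrees (0 = rightward, counterclockwise
#' positive, wrapped to (-180, 180]).
#'
#' @return Integer vector of the six direction angles in degrees.
#' @export
direction_angles <- function() c(0L, 60L, 120L, 180L, -120L, -60L)

#' Angle helpers for the six-direction task
#'
#' `wrap_angle()` wraps degrees into (-180, 180]; `snap_direction()` maps
#' arbitrary angles to the nearest of the six task directions.
#'
#' @param deg Numeric vector of angles in degrees.
#' @return `wrap_angle()`: wrapped angles; `snap_direction()`: integer
#'   angles from [direction_angles()].
#' @export
wrap_angle <- function(deg) {
  out <- (deg + 180) %% 360 - 180
  out[out == -180] <- 180
  out
}

#' @rdname wrap_angle
#' @export
snap_direction <- function(deg) {
  dirs <- direction_angles()
  dirs[max.col(-abs(outer(wrap_angle(deg), dirs, function(a, b) wrap_angle(a - b))),
               ties.method = "first")]
}

#' Enumerate the legal movement trajectories
#'
#' Of the 42 ordered (start, target) port pairs, the task uses the 30 for
#' which the two ports are adjacent (short trajectories, one spacing apart)
#' or opposite hexagon vertices (long trajectories, which pass through the
#' central port). Each of the six directions then has exactly five
#' trajectories: four short and one long.
#'
#' @param wall A `port_wall`.
#' @return Data frame with one row per trajectory: `start_port`,
#'   `target_port`, `direction` (degrees, one of [direction_angles()]) and
#'   `distance_class` (`"short"` or `"long"`).
#' @examples
#' trj <- enumerate_trajectories(build_port_wall())
#' table(trj$direction, trj$distance_class)
#' @export
enumerate_trajectories <- function(wall) {
  stopifnot(inherits(wall, "port_wall"))
  pairs <- expand.grid(start_port = 0:6, target_port = 0:6)
  pairs <- pairs[pairs$start_port != pairs$target_port, ]
  s <- port_xy(wall, pairs$start_port)
  t <- port_xy(wall, pairs$target_port)
  d <- sqrt(rowSums((t - s)^2))
  short <- abs(d - wall$spacing) < 1e-6 * wall$spacing
  long <- abs(d - 2 * wall$spacing) < 1e-6 * wall$spacing
  keep <- short | long
  out <- pairs[keep, , drop = FALSE]
  ang <- atan2(t[keep, 2] - s[keep, 2], t[keep, 1] - s[keep, 1]) * 180 / pi
  out$direction <- snap_direction(ang)
  out$distance_class <- ifelse(short[keep], "short", "long")
  out <- out[order(out$direction, out$distance_class, out$start_port), ]
  rownames(out) <- NULL
  out
}

#' Session designs of the orienting task
#'
#' Three session designs are used:
#' * `"reference"`: the 24 short trajectories, 4 per direction;
#' * `"distance"`: 18 trajectories, 3 per direction — the two short
#'   trajectories collinear with each direction (the spokes through the
#'   central port) plus the long trajectory crossing the central port;
#' * `"four_direction"`: the 16 short trajectories of the four oblique
#'   directions (+-60 and +-120 degrees).
#'
#' @param name One of `"reference"`, `"distance"`, `"four_direction"`.
#' @param wall A `port_wall` (defaults to [build_port_wall()]).
#' @param min_trials_per_condition Minimum trials required per condition for
#'   a session to be analysable (inclusion criterion; default 8).
#' @return An object of class `session_design`: list with `name`,
#'   `trajectories` (as in [enumerate_trajectories()]) and
#'   `min_trials_per_condition`.
#' @export
session_design <- function(name = c("reference", "distance", "four_direction"),
                           wall = build_port_wall(),
                           min_trials_per_condition = 8) {
  name <- match.arg(name)
  trj <- enumerate_trajectories(wall)
  trajectories <- switch(name,
    reference = trj[trj$distance_class == "short", ],
    distance = {
      # per direction: the two spokes through the centre plus the long one
      spoke <- trj$distance_class == "short" &
        (trj$start_port == 0 | trj$target_port == 0)
      trj[spoke | trj$distance_class == "long", ]
    },
    four_direction = trj[trj$distance_class == "short" &
                           !trj$direction %in% c(0L, 180L), ]
  )
  rownames(trajectories) <- NULL
  structure(
    list(name = name, wall = wall, trajectories = trajectories,
         min_trials_per_condition = min_trials_per_condition),
    class = "session_design"
  )
}

#' @export
print.session_design <- function(x, ...) {
  cat("<session_design>", x$name, "-", nrow(x$trajectories), "trajectories,",
      length(unique(x$trajectories$direction)), "directions, >=",
      x$min_trials_per_condition, "trials/condition\n")
  invisible(x)
}

#' Spatial coordinates of the three task variables for trials
#'
#' Maps each trial's start and target ports to wall coordinates and derives
#' the movement vector, so that `target = start + direction` holds exactly.
#'
#' @param trials Data frame with columns `start_port` and `target_port`
#'   (e.g. a trial table or trajectory list).
#' @param wall A `port_wall`.
#' @return Data frame with `start_x`, `start_y`, `direction_x`,
#'   `direction_y`, `target_x`, `target_y` in mm, one row per input row.
#' @export
variable_coordinates <- function(trials, wall = build_port_wall()) {
  s <- port_xy(wall, trials$start_port)
  t <- port_xy(wall, trials$target_port)
  data.frame(
    start_x = s[, 1], start_y = s[, 2],
    direction_x = t[, 1] - s[, 1], direction_y = t[, 2] - s[, 2],
    target_x = t[, 1], target_y = t[, 2]
  )
}
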