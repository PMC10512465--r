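#' Viewing geometry of the display
#'
#' Describes the planar screen the displays are projected onto: a screen at
#' `view_distance_m` subtending `field_width_deg` by `field_height_deg`,
#' refreshed at `frame_rate_hz`. All angle-to-screen conversions are
#' tan-based (gnomonic), which makes the flow-through-FoE property of pure
#' translation exact on the screen plane.
#'
#' @param view_distance_m Eye-to-screen distance in meters.
#' @param field_width_deg,field_height_deg Field extent in degrees (< 180).
#' @param frame_rate_hz Display refresh rate, frames per second.
#' @return An object of class `viewing_geometry`.
#' @export
#' @examples
#' geom <- viewing_geometry()
#' deg_to_screen(45, geom)  # equals the viewing distance
viewing_geometry <- function(view_distance_m = 0.2,
                             field_width_deg = 112,
                             field_height_deg = 80,
                             frame_rate_hz = 120) {
  stopifnot(view_distance_m > 0, frame_rate_hz > 0,
            field_width_deg > 0, field_width_deg < 180,
            field_height_deg > 0, field_height_deg < 180)
  structure(
    list(view_distance_m = view_distance_m,
         field_width_deg = field_width_deg,
         field_height_deg = field_height_deg,
         frame_rate_hz = frame_rate_hz),
    class = "viewing_geometry"
  )
}

#' Convert a visual angle to a screen offset (and back)
#'
#' Planar-perspective convention: an eccentricity of `a` degrees maps to a
#' screen offset of `view_distance_m * tan(a)` from the screen center, per
#' axis. `screen_to_deg()` is the exact inverse.
#'
#' @param angle_deg Visual angle in degrees; must satisfy |angle| < 90.
#' @param geom A [viewing_geometry()].
#' @return Screen offset in the unit of `view_distance_m` (meters).
#' @export
deg_to_screen <- function(angle_deg, geom = viewing_geometry()) {
  if (any(abs(angle_deg) >= 90)) {
    abort("|angle_deg| must be < 90 for planar projection")
  }
  geom$view_distance_m * tan(angle_deg * pi / 180)
}

#' @rdname deg_to_screen
#' @param offset_m Screen offset in meters.
#' @export
screen_to_deg <- function(offset_m, geom = viewing_geometry()) {
  atan(offset_m / geom$view_distance_m) * 180 / pi
}

#' Dot counts of the two density levels
#'
#' High density is 90 dots (45 Glass-pattern pairs); low density is 28 dots
#' (14 pairs). Over the 112 x 80 degree field these give 0.01 and 0.003
#' dots per square degree.
#'
#' @param modality `"form"` or `"motion"`.
#' @param density `"low"` or `"high"`.
#' @return For form, the number of dot pairs; for motion, the number of dots.
#' @export
density_dot_count <- function(modality = c("form", "motion"),
                              density = c("high", "low")) {
  modality <- match.arg(modality)
  density <- match.arg(density)
  counts <- list(form = c(high = 45L, low = 14L),
                 motion = c(high = 90L, low = 28L))
  unname(counts[[modality]][density])
}

#' Generate a Glass-pattern (form) display
#'
#' `n_pairs` dot pairs are placed at centers uniform over the field; each
#' pair is laid out along the screen-plane direction from its center to the
#' form focus of expansion, so that the line through every pair passes
#' through the FoE point. The FoE lies on the horizontal meridian
#' (vertical coordinate 0), matching a response probe restricted to the
#' horizontal line.
#'
#' @param foe_deg Horizontal angle of the form FoE, degrees in \[-45, 45\].
#' @param n_pairs Number of dot pairs (45 high density, 14 low density).
#' @param geom A [viewing_geometry()].
#' @param pair_separation_deg Within-pair dot separation, degrees (converted
#'   to a screen length via [deg_to_screen()]).
#' @param dot_diameter_deg Dot diameter, degrees; metadata only, never
#'   rasterized.
#' @param seed Optional integer seed for reproducible placement.
#' @return An object of class `form_display`: the parameters plus a tibble
#'   `pairs` with pair centers and the two dot positions in screen meters
#'   and degrees.
#' @export
#' @examples
#' d <- make_form_display(foe_deg = 10, n_pairs = 45, seed = 1)
#' form_collinearity_error(d)  # ~ 0
make_form_display <- function(foe_deg, n_pairs = 45,
                              geom = viewing_geometry(),
                              pair_separation_deg = 1,
                              dot_diameter_deg = 0.28,
                              seed = NULL) {
  stopifnot(abs(foe_deg) <= 45, n_pairs >= 1)
  area <- geom$field_width_deg * geom$field_height_deg
  if (2 * n_pairs / area > 1) {
    abort("n_pairs too large for overlap-free placement at this field size")
  }
  if (!is.null(seed)) set.seed(seed)
  cx_deg <- runif(n_pairs, -geom$field_width_deg / 2, geom$field_width_deg / 2)
  cy_deg <- runif(n_pairs, -geom$field_height_deg / 2, geom$field_height_deg / 2)
  cx <- deg_to_screen(cx_deg, geom)
  cy <- deg_to_screen(cy_deg, geom)
  foe_x <- deg_to_screen(foe_deg, geom)
  ux <- foe_x - cx
  uy <- 0 - cy
  nrm <- sqrt(ux^2 + uy^2)
  # a center exactly on the FoE has no defined orientation; use horizontal
  degen <- nrm < 1e-12
  ux <- ifelse(degen, 1, ux / pmax(nrm, 1e-12))
  uy <- ifelse(degen, 0, uy / pmax(nrm, 1e-12))
  half <- deg_to_screen(pair_separation_deg, geom) / 2
  pairs <- tibble::tibble(
    pair = seq_len(n_pairs),
    center_x_deg = cx_deg, center_y_deg = cy_deg,
    center_x_m = cx, center_y_m = cy,
    dot1_x_m = cx - ux * half, dot1_y_m = cy - uy * half,
    dot2_x_m = cx + ux * half, dot2_y_m = cy + uy * half
  )
  pairs$dot1_x_deg <- screen_to_deg(pairs$dot1_x_m, geom)
  pairs$dot1_y_deg <- screen_to_deg(pairs$dot1_y_m, geom)
  pairs$dot2_x_deg <- screen_to_deg(pairs$dot2_x_m, geom)
  pairs$dot2_y_deg <- screen_to_deg(pairs$dot2_y_m, geom)
  structure(
    list(foe_deg = foe_deg, n_pairs = as.integer(n_pairs),
         pair_separation_deg = pair_separation_deg,
         dot_diameter_deg = dot_diameter_deg,
         geom = geom, pairs = pairs),
    class = "form_display"
  )
}

#' Generate a translational optic-flow (motion) display
#'
#' Simulates an observer translating at `speed_m_s` through a 3D dot cloud.
#' The heading has horizontal angle `heading_deg` (vertical component 0):
#' the translation vector is `speed * (sin h, 0, cos h)` in the observer
#' frame. Per frame, every dot's observer-frame position is decremented by
#' `translation * dt` and reprojected onto the planar screen; dots crossing
#' the near depth bound or leaving the field are recycled to a fresh uniform
#' image position and depth. Under pure translation, every non-recycled
#' frame-to-frame image displacement lies on a line through the motion FoE
#' image point `deg_to_screen(heading_deg)`.
#'
#' @param heading_deg Horizontal heading angle, degrees in \[-45, 45\].
#' @param n_dots Number of dots (90 high density, 28 low density).
#' @param geom A [viewing_geometry()].
#' @param speed_m_s Translation speed, meters per second.
#' @param depth_range Length-2 numeric, near and far depth bounds in meters.
#' @param duration_s Display duration, seconds; frame count is
#'   `round(duration_s * frame_rate_hz)`.
#' @param dot_diameter_deg Dot diameter, degrees; metadata only.
#' @param seed Optional integer seed.
#' @return An object of class `motion_display`: the parameters plus a long
#'   tibble `frames` (frame, dot, 3D position in meters, image position in
#'   screen meters, and a `recycled` flag marking fresh re-entries whose
#'   displacement from the previous frame is not a flow vector).
#' @export
make_motion_display <- function(heading_deg, n_dots = 90,
                                geom = viewing_geometry(),
                                speed_m_s = 1.5,
                                depth_range = c(0.2, 5),
                                duration_s = 0.5,
                                dot_diameter_deg = 0.28,
                                seed = NULL) {
  stopifnot(abs(heading_deg) <= 45, n_dots >= 1,
            length(depth_range) == 2, depth_range[1] < depth_range[2])
  if (speed_m_s <= 0) abort("`speed_m_s` must be positive")
  if (duration_s <= 0) abort("`duration_s` must be positive")
  if (!is.null(seed)) set.seed(seed)
  n_frames <- round(duration_s * geom$frame_rate_hz)
  dt <- 1 / geom$frame_rate_hz
  h <- heading_deg * pi / 180
  trans <- speed_m_s * c(sin(h), 0, cos(h)) * dt
  half_w <- geom$field_width_deg / 2
  half_h <- geom$field_height_deg / 2

  sample_dots <- function(n) {
    x_deg <- runif(n, -half_w, half_w)
    y_deg <- runif(n, -half_h, half_h)
    z <- runif(n, depth_range[1], depth_range[2])
    # image position (deg) and depth determine the 3D point
    list(X = tan(x_deg * pi / 180) * z, Y = tan(y_deg * pi / 180) * z, Z = z)
  }

  p <- sample_dots(n_dots)
  frames <- vector("list", n_frames)
  frames[[1]] <- tibble::tibble(
    frame = 1L, dot = seq_len(n_dots),
    X = p$X, Y = p$Y, Z = p$Z, recycled = FALSE
  )
  for (f in seq_len(n_frames)[-1]) {
    X <- p$X - trans[1]; Y <- p$Y - trans[2]; Z <- p$Z - trans[3]
    x_deg <- atan2(X, Z) * 180 / pi
    y_deg <- atan2(Y, Z) * 180 / pi
    out <- Z < depth_range[1] | Z > depth_range[2] |
      abs(x_deg) > half_w | abs(y_deg) > half_h
    if (any(out)) {
      fresh <- sample_dots(sum(out))
      X[out] <- fresh$X; Y[out] <- fresh$Y; Z[out] <- fresh$Z
    }
    p <- list(X = X, Y = Y, Z = Z)
    frames[[f]] <- tibble::tibble(
      frame = f, dot = seq_len(n_dots),
      X = X, Y = Y, Z = Z, recycled = out
    )
  }
  frames <- dplyr::bind_rows(frames)
  frames$x_img_m <- geom$view_distance_m * frames$X / frames$Z
  frames$y_img_m <- geom$view_distance_m * frames$Y / frames$Z
  structure(
    list(heading_deg = heading_deg, n_dots = as.integer(n_dots),
         speed_m_s = speed_m_s, depth_range = depth_range,
         duration_s = duration_s, n_frames = as.integer(n_frames),
         dot_diameter_deg = dot_diameter_deg,
         geom = geom, frames = frames),
    class = "motion_display"
  )
}

#' Dot density of a display
#'
#' Dot count divided by the field area in square degrees. A pair counts as
#' two dots.
#'
#' @param display A `form_display` or `motion_display`.
#' @return Dots per square degree.
#' @export
#' @examples
#' display_density(make_motion_display(0, n_dots = 90, seed = 1))  # ~0.01
display_density <- function(display) {
  geom <- display$geom
  n <- if (inherits(display, "form_display")) 2L * display$n_pairs else display$n_dots
  n / (geom$field_width_deg * geom$field_height_deg)
}

#' Maximum FoE-collinearity residual of a form display
#'
#' For each dot pair, the perpendicular distance (screen meters) from the
#' form-FoE screen point to the infinite line through the pair's two dots.
#' By construction this is numerically zero.
#'
#' @param display A `form_display`.
#' @return The maximum perpendicular distance over pairs, in screen meters.
#' @export
form_collinearity_error <- function(display) {
  p <- display$pairs
  fx <- deg_to_screen(display$foe_deg, display$geom)
  dx <- p$dot2_x_m - p$dot1_x_m
  dy <- p$dot2_y_m - p$dot1_y_m
  nrm <- sqrt(dx^2 + dy^2)
  # 2D cross product of (foe - dot1) with the unit pair direction
  max(abs((fx - p$dot1_x_m) * dy / nrm - (0 - p$dot1_y_m) * dx / nrm))
}

#' Recover the focus of expansion from a motion display's flow field
#'
#' Least-squares intersection of all non-recycled frame-to-frame image
#' displacement lines: the screen point minimizing the summed squared
#' perpendicular distance to every displacement's supporting line. Under
#' pure translation this equals the projected heading point exactly.
#'
#' @param display A `motion_display`.
#' @return A list with `x_m`, `y_m` (screen meters), `x_deg` (degrees), and
#'   `max_line_dist_m`, the largest perpendicular distance from the
#'   recovered point to any displacement line.
#' @export
estimate_motion_foe <- function(display) {
  fr <- display$frames
  fr <- fr[order(fr$dot, fr$frame), ]
  n_f <- display$n_frames
  cur <- fr[fr$frame > 1, ]
  prev <- fr[fr$frame < n_f, ]
  keep <- !cur$recycled
  p1x <- prev$x_img_m[keep]; p1y <- prev$y_img_m[keep]
  dx <- cur$x_img_m[keep] - p1x
  dy <- cur$y_img_m[keep] - p1y
  nrm <- sqrt(dx^2 + dy^2)
  ok <- nrm > 1e-15
  ux <- dx[ok] / nrm[ok]; uy <- dy[ok] / nrm[ok]
  px <- p1x[ok]; py <- p1y[ok]
  # minimize sum |(I - uu')(q - p)|^2 over q: normal equations in 2D
  a11 <- sum(1 - ux^2); a12 <- sum(-ux * uy); a22 <- sum(1 - uy^2)
  b1 <- sum((1 - ux^2) * px - ux * uy * py)
  b2 <- sum(-ux * uy * px + (1 - uy^2) * py)
  det <- a11 * a22 - a12^2
  if (abs(det) < 1e-20) abort("flow field is degenerate; cannot locate FoE")
  qx <- (a22 * b1 - a12 * b2) / det
  qy <- (a11 * b2 - a12 * b1) / det
  dist <- abs((qx - px) * uy - (qy - py) * ux)
  list(x_m = qx, y_m = qy,
       x_deg = screen_to_deg(qx, display$geom),
       max_line_dist_m = max(dist))
}

#' Export a display specification as JSON
#'
#' Writes the display parameters and dot coordinate table to a structured
#' text file for inspection or external rendering.
#'
#' @param display A `form_display` or `motion_display`.
#' @param path Destination `.json` path.
#' @return `path`, invisibly.
#' @export
write_display_spec <- function(display, path) {
  x <- unclass(display)
  x$geom <- unclass(x$geom)
  x$type <- if (inherits(display, "form_display")) "form" else "motion"
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @export
print.form_display <- function(x, ...) {
  cat(sprintf("<form_display> FoE %g deg, %d dot pairs (%.3g dots/deg^2)\n",
              x$foe_deg, x$n_pairs, display_density(x)))
  invisible(x)
}

#' @export
print.motion_display <- function(x, ...) {
  cat(sprintf(
    "<motion_display> heading %g deg, %d dots, %d frames, %.3g dots/deg^2\n",
    x$heading_deg, x$n_dots, x$n_frames, display_density(x)))
  invisible(x)
}
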