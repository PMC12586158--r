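# Stimulus battery: parametric construction and rasterization of the
# illusory-contour image set, plus the geometric audits (ink overlap,
# support ratio, receptive-field mapping grid).
#
# Geometry conventions: visual degrees, origin at the canvas center,
# x rightward, y upward.  Orientations are measured clockwise from the
# vertical, in [0, 180).  The illusory bar of I_C1 lies at 135 degrees
# (connecting the top-left and bottom-right circles), the bar of I_C2 at
# 45 degrees (bottom-left to top-right).

#' Stimulus specification
#'
#' Parameters of the four-circle illusory-contour battery.  The defaults
#' reproduce the study geometry: 30-degree circles whose diagonal centers
#' are 46 degrees apart (16-degree illusory gap), 16-degree inducer bars
#' (support ratio 2/3) and real-edge outlines 2 degrees thick.
#'
#' @param circle_diameter_deg Diameter of the four circles (degrees).
#' @param diag_center_dist_deg Distance between centers of diagonally
#'   opposite circles (degrees). Must exceed the circle diameter so that a
#'   positive illusory gap remains.
#' @param inducer_bar_len_deg Length of the bar segment drawn on each
#'   inducer circle (degrees).
#' @param bar_outline_thickness_deg Thickness of the outline delimiting
#'   real bars in the real-edge images (degrees, at least 2 so the edge is
#'   comfortably above mouse acuity).
#' @param bar_width_deg Width of the (illusory or real) bar (degrees).
#' @param configuration `"cfg1"` (canonical) or `"cfg0"` (the whole
#'   geometry rotated 315 degrees clockwise before rasterization).
#' @param polarity `"white_on_black"` (white circles, black ink) or
#'   `"black_on_white"` (gray levels off the background flipped).
#' @param raster_ppd Raster resolution in pixels per degree (at least 2 so
#'   the 2-degree outline maps to >= 4 pixels).
#' @param canvas_deg Width and height of the rendered field (degrees).
#' @return An object of class `stimulus_spec`.
#' @export
stimulus_spec <- function(circle_diameter_deg = 30,
                          diag_center_dist_deg = 46,
                          inducer_bar_len_deg = 16,
                          bar_outline_thickness_deg = 2,
                          bar_width_deg = 8,
                          configuration = c("cfg1", "cfg0"),
                          polarity = c("white_on_black", "black_on_white"),
                          raster_ppd = 4,
                          canvas_deg = c(96, 96)) {
  configuration <- match.arg(configuration)
  polarity <- match.arg(polarity)
  if (diag_center_dist_deg <= circle_diameter_deg)
    stop("diag_center_dist_deg must exceed circle_diameter_deg (positive gap)")
  if (bar_outline_thickness_deg < 2)
    stop("bar_outline_thickness_deg must be >= 2 degrees")
  if (raster_ppd < 2)
    stop("raster too coarse to represent the outline thickness (raster_ppd must be >= 2)")
  if (inducer_bar_len_deg < 0) stop("inducer_bar_len_deg must be non-negative")
  spec <- list(circle_diameter_deg = circle_diameter_deg,
               diag_center_dist_deg = diag_center_dist_deg,
               inducer_bar_len_deg = inducer_bar_len_deg,
               bar_outline_thickness_deg = bar_outline_thickness_deg,
               bar_width_deg = bar_width_deg,
               configuration = configuration,
               polarity = polarity,
               raster_ppd = raster_ppd,
               canvas_deg = rep_len(canvas_deg, 2))
  class(spec) <- "stimulus_spec"
  spec
}

#' @export
print.stimulus_spec <- function(x, ...) {
  cat("Stimulus spec:", x$configuration, x$polarity, "\n")
  cat(sprintf("  circles %g deg, diagonal centers %g deg apart (gap %g deg)\n",
              x$circle_diameter_deg, x$diag_center_dist_deg,
              x$diag_center_dist_deg - x$circle_diameter_deg))
  cat(sprintf("  inducer bars %g deg (support ratio %.3f), bar width %g deg, outline %g deg\n",
              x$inducer_bar_len_deg, support_ratio(x), x$bar_width_deg,
              x$bar_outline_thickness_deg))
  cat(sprintf("  raster %g px/deg on %g x %g deg canvas\n",
              x$raster_ppd, x$canvas_deg[1], x$canvas_deg[2]))
  invisible(x)
}

#' Illusory-contour support ratio
#'
#' Fraction of the illusory bar physically supported by inducer ink:
#' `2 L / (2 L + gap)` with `gap = diag_center_dist - circle_diameter`.
#'
#' @param spec A [stimulus_spec()].
#' @return Support ratio in `[0, 1]`.
#' @export
support_ratio <- function(spec) {
  gap <- spec$diag_center_dist_deg - spec$circle_diameter_deg
  L <- spec$inducer_bar_len_deg
  if (L == 0 && gap == 0) return(NaN)
  (2 * L) / (2 * L + gap)
}

## ---- raster machinery -------------------------------------------------

# Pixel centers sit at half-integer offsets from the canvas center so the
# grid is symmetric under x -> -x and y -> -y; this makes the mirrored
# inducer segments cover exactly equal pixel counts.
raster_grid <- function(spec) {
  nx <- round(spec$canvas_deg[1] * spec$raster_ppd)
  ny <- round(spec$canvas_deg[2] * spec$raster_ppd)
  list(x = ((seq_len(nx) - 0.5) - nx / 2) / spec$raster_ppd,
       y = (ny / 2 - (seq_len(ny) - 0.5)) / spec$raster_ppd,
       nx = nx, ny = ny)
}

shape_circle <- function(cx, cy, r) list(type = "circle", cx = cx, cy = cy, r = r)
# theta: orientation of the long axis, clockwise from vertical
shape_rect <- function(cx, cy, theta, len, wid)
  list(type = "rect", cx = cx, cy = cy, theta = theta, len = len, wid = wid)

rotate_shape <- function(sh, deg_cw) {
  a <- deg_cw * pi / 180
  cx <- sh$cx * cos(a) + sh$cy * sin(a)
  cy <- -sh$cx * sin(a) + sh$cy * cos(a)
  sh$cx <- cx; sh$cy <- cy
  if (sh$type == "rect") sh$theta <- (sh$theta + deg_cw) %% 180
  sh
}

shape_mask <- function(sh, grid) {
  X <- matrix(grid$x, grid$ny, grid$nx, byrow = TRUE)
  Y <- matrix(grid$y, grid$ny, grid$nx)
  dx <- X - sh$cx; dy <- Y - sh$cy
  if (sh$type == "circle") {
    dx * dx + dy * dy <= sh$r^2
  } else {
    th <- sh$theta * pi / 180
    u <- dx * sin(th) + dy * cos(th)
    v <- dx * cos(th) - dy * sin(th)
    abs(u) <= sh$len / 2 & abs(v) <= sh$wid / 2
  }
}

render_shapes <- function(circles, ink, grid, polarity) {
  img <- matrix(0.5, grid$ny, grid$nx)
  for (sh in circles) img[shape_mask(sh, grid)] <- 1
  for (sh in ink) img[shape_mask(sh, grid)] <- 0
  if (polarity == "black_on_white") {
    off <- img != 0.5
    img[off] <- 1 - img[off]
  }
  img
}

## ---- battery geometry -------------------------------------------------

# Primitive (circle + ink shape) lists for every labeled image, in cfg1
# geometry.  cfg0 is obtained by rotating every primitive 315 degrees
# clockwise before rasterization (no image resampling).
battery_primitives <- function(spec) {
  r <- spec$circle_diameter_deg / 2
  cc <- spec$diag_center_dist_deg / 2
  gap <- spec$diag_center_dist_deg - spec$circle_diameter_deg
  L <- spec$inducer_bar_len_deg
  w <- spec$bar_width_deg
  thk <- spec$bar_outline_thickness_deg
  axis_dir <- function(theta) c(sin(theta * pi / 180), cos(theta * pi / 180))
  perp_dir <- function(theta) c(cos(theta * pi / 180), -sin(theta * pi / 180))

  # circle centers: along the 135-degree axis u = +cc is bottom-right,
  # u = -cc top-left; along the 45-degree axis u = +cc is top-right.
  quads <- list(BR = list(theta = 135, u = +cc),
                TL = list(theta = 135, u = -cc),
                TR = list(theta = 45,  u = +cc),
                BL = list(theta = 45,  u = -cc))
  circles <- lapply(quads, function(q) {
    p <- q$u * axis_dir(q$theta)
    shape_circle(p[1], p[2], r)
  })

  seg <- function(quad, inward) {
    q <- quads[[quad]]
    u_in <- sign(q$u) * (gap / 2 + L / 2)
    u <- if (inward) u_in else 2 * q$u - u_in
    p <- u * axis_dir(q$theta)
    shape_rect(p[1], p[2], q$theta, L, w)
  }

  # Real-edge bar outline: two flanking strips just outside the bar
  # region (so outline ink never intersects inducer fill), plus end caps
  # for full-length bars.  The gap-spanning outline used in T_RE has no
  # end caps: its ends abut the inducer segment and the opposite circle.
  outline_strips <- function(theta, len) {
    d <- axis_dir(theta); p <- perp_dir(theta)
    v <- w / 2 + thk / 2
    list(shape_rect(v * p[1], v * p[2], theta, len, thk),
         shape_rect(-v * p[1], -v * p[2], theta, len, thk))
  }
  outline_caps <- function(theta, len) {
    d <- axis_dir(theta)
    u <- len / 2 + thk / 2
    list(shape_rect(u * d[1], u * d[2], theta, thk, w + 2 * thk),
         shape_rect(-u * d[1], -u * d[2], theta, thk, w + 2 * thk))
  }
  full_len <- 2 * L + gap
  real_bar <- function(theta) c(outline_strips(theta, full_len),
                                outline_caps(theta, full_len))

  imgs <- list(
    I_C1 = list(seg("BR", TRUE), seg("TL", TRUE)),
    I_C2 = list(seg("TR", TRUE), seg("BL", TRUE)),
    L_C1 = list(seg("BR", TRUE), seg("TR", TRUE)),
    L_C2 = list(seg("TL", TRUE), seg("BL", TRUE)),
    T_RE1 = c(list(seg("BR", TRUE)), outline_strips(135, gap)),
    T_RE2 = c(list(seg("BL", TRUE)), outline_strips(45, gap)),
    X_RE1 = real_bar(135),
    X_RE2 = real_bar(45),
    I_RE_0 = real_bar(0),
    I_RE_45 = real_bar(45),
    I_RE_90 = real_bar(90),
    I_RE_135 = real_bar(135),
    In_BR = list(seg("BR", TRUE)),  Out_BR = list(seg("BR", FALSE)),
    In_BL = list(seg("BL", TRUE)),  Out_BL = list(seg("BL", FALSE)),
    In_TL = list(seg("TL", TRUE)),  Out_TL = list(seg("TL", FALSE)),
    In_TR = list(seg("TR", TRUE)),  Out_TR = list(seg("TR", FALSE)),
    blank_circles = list(),
    gray = list()
  )
  list(circles = circles, ink = imgs)
}

#' Render the full stimulus battery
#'
#' Rasterizes every labeled image of the battery (illusory I_C pair,
#' recombined L_C pair, real-edge probes T_RE / X_RE / I_RE, single
#' inward/outward inducer segments, blank circles, gray screen) on a
#' common grid.  All labeled images except `gray` share an identical
#' four-circle layer; ink masks mark pixels that differ from both the
#' background and the circle layer, so the circles (which persist through
#' the inter-trial interval and carry no discriminative pixels) are
#' excluded from every overlap computation.
#'
#' @param spec A [stimulus_spec()].
#' @return An object of class `stimulus_set`: list with `images` (named
#'   list; each image has `pixels` in `[0,1]` and logical `ink`), `spec`
#'   and `grid`.
#' @export
render_battery <- function(spec) {
  grid <- raster_grid(spec)
  prim <- battery_primitives(spec)
  rot <- if (spec$configuration == "cfg0") 315 else 0
  circles <- lapply(prim$circles, rotate_shape, deg_cw = rot)

  blank <- render_shapes(circles, list(), grid, spec$polarity)
  images <- lapply(names(prim$ink), function(lab) {
    if (lab == "gray") {
      px <- matrix(0.5, grid$ny, grid$nx)
    } else {
      ink_shapes <- lapply(prim$ink[[lab]], rotate_shape, deg_cw = rot)
      px <- render_shapes(circles, ink_shapes, grid, spec$polarity)
    }
    list(label = lab, pixels = px, ink = px != blank & px != 0.5)
  })
  names(images) <- names(prim$ink)
  structure(list(images = images, spec = spec, grid = grid),
            class = "stimulus_set")
}

#' @export
print.stimulus_set <- function(x, ...) {
  cat("Stimulus set:", length(x$images), "images at",
      x$grid$ny, "x", x$grid$nx, "px\n")
  cat(" ", paste(names(x$images), collapse = ", "), "\n")
  invisible(x)
}

#' Normalized ink overlap between two images
#'
#' Jaccard fraction `|ink(a) & ink(b)| / |ink(a) | ink(b)|` of the ink
#' masks (background and the shared circle layer excluded).
#'
#' @param a,b Images from a [render_battery()] set (elements of
#'   `set$images`), or logical ink masks.
#' @return Overlap fraction in `[0, 1]` (1 for identical masks).
#' @export
pixel_overlap <- function(a, b) {
  ma <- if (is.list(a)) a$ink else a
  mb <- if (is.list(b)) b$ink else b
  if (!all(dim(ma) == dim(mb)))
    stop("pixel_overlap: images are on different raster grids")
  if (identical(ma, mb)) return(1)
  un <- sum(ma | mb)
  if (un == 0) return(0)
  sum(ma & mb) / un
}

#' Pairwise ink-overlap matrix of a stimulus set
#'
#' @param set A `stimulus_set`.
#' @param labels Image labels to include (default: all except `gray`).
#' @return List with `counts` (pairwise ink-intersection pixel counts) and
#'   `fraction` (normalized overlap; symmetric, unit diagonal).
#' @export
overlap_matrix <- function(set, labels = setdiff(names(set$images), "gray")) {
  masks <- lapply(set$images[labels], `[[`, "ink")
  n <- length(masks)
  counts <- matrix(0L, n, n, dimnames = list(labels, labels))
  frac <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n)) for (j in i:n) {
    counts[i, j] <- counts[j, i] <- sum(masks[[i]] & masks[[j]])
    frac[i, j] <- frac[j, i] <- pixel_overlap(masks[[i]], masks[[j]])
  }
  diag(frac) <- 1
  list(counts = counts, fraction = frac)
}

#' Receptive-field mapping grid
#'
#' Nine 16-degree grating-patch positions: one at the canvas center
#' (coinciding with the illusory gap region) and eight at 16 degrees
#' eccentricity at clock positions 6, 4.5, 3, 1.5, 12, 10.5, 9 and 7.5.
#'
#' @param spec A [stimulus_spec()] (unused geometry fields are ignored;
#'   kept so grids follow the spec's conventions).
#' @param eccentricity_deg Distance of peripheral patches from the center.
#' @param patch_diameter_deg Patch diameter.
#' @return data.frame with `position` (1 = center), `clock`, `x_deg`,
#'   `y_deg`, `diameter_deg`.
#' @export
rf_mapping_grid <- function(spec = stimulus_spec(), eccentricity_deg = 16,
                            patch_diameter_deg = 16) {
  clock <- c(NA, 6, 4.5, 3, 1.5, 12, 10.5, 9, 7.5)
  ang <- clock * 30 * pi / 180  # clockwise from 12 o'clock
  data.frame(position = 1:9,
             clock = clock,
             x_deg = c(0, eccentricity_deg * sin(ang[-1])),
             y_deg = c(0, eccentricity_deg * cos(ang[-1])),
             diameter_deg = patch_diameter_deg)
}

# Rasterized grating-patch stand-ins for the receptive-field mapping
# block: full-contrast discs on the gray background.  Used by the
# population simulator to produce mapping-block drives.
rf_patch_images <- function(spec, grid = raster_grid(spec)) {
  g <- rf_mapping_grid(spec)
  imgs <- lapply(seq_len(nrow(g)), function(i) {
    sh <- shape_circle(g$x_deg[i], g$y_deg[i], g$diameter_deg[i] / 2)
    px <- matrix(0.5, grid$ny, grid$nx)
    px[shape_mask(sh, grid)] <- 1
    list(label = paste0("rf_pos_", i), pixels = px, ink = px != 0.5)
  })
  names(imgs) <- vapply(imgs, `[[`, "", "label")
  imgs
}

#' Write a stimulus set to disk
#'
#' Writes one 8-bit grayscale PNG per image (requires the `png` package),
#' the spec as JSON, and the normalized overlap matrix as CSV.
#'
#' @param set A `stimulus_set`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the directory.
#' @export
write_stimuli <- function(set, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (requireNamespace("png", quietly = TRUE)) {
    for (img in set$images)
      png::writePNG(img$pixels, file.path(dir, paste0(img$label, ".png")))
  } else {
    warning("package 'png' not available; skipping PNG output")
  }
  jsonlite::write_json(unclass(set$spec), file.path(dir, "spec.json"),
                       auto_unbox = TRUE, digits = NA)
  om <- overlap_matrix(set)
  utils::write.csv(om$fraction, file.path(dir, "overlap_fraction.csv"))
  invisible(dir)
}
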