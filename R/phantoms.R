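#' @name phantoms
#' @title Synthetic ileus phantom generation
#' @description
#' Generates 2-D grayscale phantoms that emulate the MRI phenomenology of
#' mechanical bowel obstruction: dilated bowel loops (ellipses) containing
#' an air--fluid level (dark gas above a horizontal interface, bright fluid
#' below, as on T2-weighted images), and an optional soft-tissue mass with
#' an irregularly thickened wall.  Every phantom carries a pixel-exact
#' ground-truth mask (0 background, 1 lumen, 2 lesion) so the whole
#' segmentation pipeline is testable without clinical data.
NULL

PHANTOM_CLASSES <- c("sist", "colon_cancer", "adhesive", "volvulus")

#' Describe one dilated bowel loop
#'
#' @param center numeric length-2 `(row, col)` in pixels
#' @param semi_axes numeric length-2 `(a, b)` ellipse semi-axes in pixels
#' @param angle orientation of the first axis, radians (counter-clockwise)
#' @param lumen_level fluid intensity in `[0,1]` (bright on T2)
#' @return a `loop_spec` list
#' @export
loop_spec <- function(center, semi_axes, angle = 0, lumen_level = 0.85) {
  check(length(center) == 2 && all(is.finite(center)), "center must be (row, col)")
  check(length(semi_axes) == 2 && all(semi_axes > 0), "semi_axes must be positive")
  check(is.finite(angle), "angle must be finite")
  check(lumen_level >= 0 && lumen_level <= 1, "lumen_level must lie in [0,1]")
  structure(list(center = as.numeric(center), semi_axes = as.numeric(semi_axes),
                 angle = as.numeric(angle), lumen_level = as.numeric(lumen_level)),
            class = "loop_spec")
}

#' Describe a soft-tissue mass with irregular wall thickening
#'
#' @inheritParams loop_spec
#' @param level interior intensity in `[0,1]`
#' @param wall_thickness wall band thickness in pixels (radially)
#' @param wall_level wall intensity in `[0,1]`
#' @param irregularity relative amplitude of the angular boundary
#'   perturbation that renders the wall "irregularly thickened"
#' @return a `lesion_spec` list
#' @export
lesion_spec <- function(center, semi_axes, angle = 0, level = 0.68,
                        wall_thickness = 3, wall_level = 0.20,
                        irregularity = 0.15) {
  check(length(center) == 2 && all(is.finite(center)), "center must be (row, col)")
  check(length(semi_axes) == 2 && all(semi_axes > 0), "semi_axes must be positive")
  check(level >= 0 && level <= 1, "level must lie in [0,1]")
  check(wall_level >= 0 && wall_level <= 1, "wall_level must lie in [0,1]")
  check(wall_thickness >= 0, "wall_thickness must be >= 0")
  check(irregularity >= 0 && irregularity < 1, "irregularity must lie in [0,1)")
  structure(list(center = as.numeric(center), semi_axes = as.numeric(semi_axes),
                 angle = as.numeric(angle), level = level,
                 wall_thickness = wall_thickness, wall_level = wall_level,
                 irregularity = irregularity),
            class = "lesion_spec")
}

#' Full phantom description
#'
#' @param height,width image size in pixels
#' @param background_level soft-tissue background intensity in `[0,1]`
#' @param loops list of [loop_spec()] objects
#' @param airfluid_fraction fraction of each loop's height rendered as dark
#'   gas above the horizontal air--fluid interface
#' @param lesion a [lesion_spec()] or `NULL`
#' @param noise_sd additive zero-mean noise standard deviation (intensity units)
#' @param class_label one of `"sist"`, `"colon_cancer"`, `"adhesive"`,
#'   `"volvulus"` -- the morphology archetype this phantom emulates
#' @param air_level gas intensity in `[0,1]`
#' @return a `phantom_spec` list
#' @export
phantom_spec <- function(height, width, background_level = 0.40,
                         loops = list(), airfluid_fraction = 0.4,
                         lesion = NULL, noise_sd = 0.05,
                         class_label = "sist", air_level = 0.05) {
  check(is_count(height) && is_count(width), "height and width must be positive integers")
  check(background_level >= 0 && background_level <= 1,
        "background_level must lie in [0,1]")
  check(airfluid_fraction >= 0 && airfluid_fraction <= 1,
        "airfluid_fraction must lie in [0,1]")
  check(air_level >= 0 && air_level <= 1, "air_level must lie in [0,1]")
  check(noise_sd >= 0, "noise_sd must be >= 0")
  check(class_label %in% PHANTOM_CLASSES,
        sprintf("class_label must be one of: %s", paste(PHANTOM_CLASSES, collapse = ", ")))
  check(is.null(lesion) || inherits(lesion, "lesion_spec"),
        "lesion must be NULL or a lesion_spec")
  for (lp in loops) check(inherits(lp, "loop_spec"), "loops must be loop_spec objects")
  structure(list(height = as.integer(height), width = as.integer(width),
                 background_level = background_level, loops = loops,
                 airfluid_fraction = airfluid_fraction, lesion = lesion,
                 noise_sd = noise_sd, class_label = class_label,
                 air_level = air_level),
            class = "phantom_spec")
}

# Squared normalized elliptical radius of every grid pixel, after rotating
# into the ellipse frame.  Returns a height x width matrix.
ellipse_r2 <- function(height, width, center, semi_axes, angle) {
  rr <- matrix(seq_len(height), height, width) - center[1]
  cc <- matrix(seq_len(width), height, width, byrow = TRUE) - center[2]
  u <- ( cos(angle) * rr + sin(angle) * cc) / semi_axes[1]
  v <- (-sin(angle) * rr + cos(angle) * cc) / semi_axes[2]
  list(r2 = u * u + v * v, theta = atan2(v, u))
}

#' Render one phantom with its ground-truth mask
#'
#' Deterministic for a fixed `(spec, seed)`.  The truth mask is drawn before
#' noise; noise is additive, zero-mean Gaussian with `sd = noise_sd`,
#' clipped to `[0,1]` (a Rician magnitude model is available via
#' `noise_model = "rician"`, in which the noisy image is
#' `sqrt((I + e1)^2 + e2^2)` with independent Gaussian `e1, e2`).
#'
#' @param spec a [phantom_spec()]
#' @param seed integer seed for the noise draw
#' @param noise_model `"gaussian"` (default) or `"rician"`
#' @return a `labeled_image_pair` list with elements `image` (matrix in
#'   `[0,1]`), `truth` (integer matrix, 0 background / 1 lumen / 2 lesion),
#'   `spec`, and `seed`
#' @export
#' @examples
#' sp <- phantom_spec(64, 64, loops = list(loop_spec(c(32, 32), c(18, 12))),
#'                    noise_sd = 0)
#' pair <- make_phantom(sp, seed = 1)
#' table(pair$truth)
make_phantom <- function(spec, seed = 0L, noise_model = c("gaussian", "rician")) {
  check(inherits(spec, "phantom_spec"), "spec must be a phantom_spec")
  noise_model <- match.arg(noise_model)
  h <- spec$height; w <- spec$width
  img <- matrix(spec$background_level, h, w)
  truth <- matrix(0L, h, w)

  rows <- matrix(seq_len(h), h, w)
  for (lp in spec$loops) {
    e <- ellipse_r2(h, w, lp$center, lp$semi_axes, lp$angle)
    inside <- e$r2 <= 1
    # vertical extent of the rotated ellipse: half-height in image rows
    half_h <- sqrt((lp$semi_axes[1] * cos(lp$angle))^2 +
                   (lp$semi_axes[2] * sin(lp$angle))^2)
    interface_row <- lp$center[1] - half_h + spec$airfluid_fraction * 2 * half_h
    air <- inside & (rows < interface_row)
    img[inside] <- lp$lumen_level
    img[air] <- spec$air_level
    truth[inside] <- 1L
  }

  ls <- spec$lesion
  if (!is.null(ls)) {
    e <- ellipse_r2(h, w, ls$center, ls$semi_axes, ls$angle)
    # irregular wall: boundary radius modulated around the ellipse
    mod <- 1 + ls$irregularity * sin(5 * e$theta + 1.3)
    wall_frac <- ls$wall_thickness / mean(ls$semi_axes)
    outer <- sqrt(e$r2) <= mod
    inner <- sqrt(e$r2) <= pmax(mod - wall_frac, 0)
    img[outer] <- ls$wall_level
    img[inner] <- ls$level
    truth[outer] <- 2L
  }

  if (spec$noise_sd > 0) {
    img <- with_seed(seed, {
      if (noise_model == "gaussian") {
        img + matrix(rnorm(h * w, 0, spec$noise_sd), h, w)
      } else {
        e1 <- matrix(rnorm(h * w, 0, spec$noise_sd), h, w)
        e2 <- matrix(rnorm(h * w, 0, spec$noise_sd), h, w)
        sqrt((img + e1)^2 + e2^2)
      }
    })
    img <- clamp(img, 0, 1)
  }

  structure(list(image = img, truth = truth, spec = spec, seed = as.integer(seed)),
            class = "labeled_image_pair")
}

# Parameter template per morphology archetype, in relative coordinates
# scaled by the image size.  Each archetype maps to a distinct template:
#  sist          - one dilated loop + a large round mass, thin wall
#  colon_cancer  - two loops + an elongated mass with a very thick wall
#  adhesive      - three small loops, no mass
#  volvulus      - two long crossed loops + a small bright mass
phantom_template <- function(class_label, size = 256L, noise_sd = 0.05,
                             background = 0.40, air_level = 0.05,
                             fluid_level = 0.85) {
  s <- as.numeric(size)
  lp <- function(cr, cc, a, b, ang) loop_spec(c(cr, cc) * s, c(a, b) * s, ang, fluid_level)
  base <- function(loops, lesion)
    phantom_spec(size, size, background_level = background, loops = loops,
                 airfluid_fraction = 0.4, lesion = lesion, noise_sd = noise_sd,
                 class_label = class_label, air_level = air_level)
  switch(class_label,
    sist = base(
      list(lp(0.32, 0.30, 0.17, 0.12, 0.3)),
      lesion_spec(c(0.65, 0.62) * s, c(0.16, 0.13) * s, angle = 0.2,
                  level = 0.68, wall_thickness = 0.025 * s,
                  wall_level = 0.20, irregularity = 0.12)),
    colon_cancer = base(
      list(lp(0.26, 0.25, 0.13, 0.09, -0.4), lp(0.30, 0.68, 0.12, 0.08, 0.5)),
      lesion_spec(c(0.68, 0.45) * s, c(0.18, 0.10) * s, angle = -0.3,
                  level = 0.58, wall_thickness = 0.055 * s,
                  wall_level = 0.20, irregularity = 0.28)),
    adhesive = base(
      list(lp(0.28, 0.28, 0.10, 0.07, 0.1), lp(0.30, 0.64, 0.09, 0.06, -0.6),
           lp(0.64, 0.42, 0.11, 0.07, 0.9)),
      NULL),
    volvulus = base(
      list(lp(0.40, 0.38, 0.24, 0.08, 0.8), lp(0.46, 0.60, 0.22, 0.08, -0.8)),
      lesion_spec(c(0.74, 0.72) * s, c(0.11, 0.08) * s, angle = 0.5,
                  level = 0.78, wall_thickness = 0.015 * s,
                  wall_level = 0.25, irregularity = 0.08)),
    abort_validation(sprintf("unknown phantom class: %s", class_label)))
}

# Randomly jitter a template's geometry (centers, axes, angles) so a set of
# phantoms emulates inter-patient variation.  Draws from the current RNG.
jitter_spec <- function(spec, size) {
  jl <- function(lp) {
    loop_spec(lp$center + runif(2, -0.03, 0.03) * size,
              lp$semi_axes * runif(2, 0.85, 1.15),
              lp$angle + runif(1, -0.2, 0.2), lp$lumen_level)
  }
  spec$loops <- lapply(spec$loops, jl)
  if (!is.null(spec$lesion)) {
    ls <- spec$lesion
    spec$lesion <- lesion_spec(ls$center + runif(2, -0.03, 0.03) * size,
                               ls$semi_axes * runif(2, 0.85, 1.15),
                               ls$angle + runif(1, -0.2, 0.2), ls$level,
                               ls$wall_thickness, ls$wall_level, ls$irregularity)
  }
  spec
}

#' Generate a balanced set of phantoms across the four archetypes
#'
#' Stands in for a patient cohort: `n_per_class` phantoms per archetype,
#' each with geometry jittered around its class template and an independent
#' noise realization, all derived deterministically from one master seed.
#'
#' @param n_per_class phantoms per archetype (>= 1)
#' @param seed master seed
#' @param size image edge length in pixels
#' @param noise_sd additive noise sd
#' @param template_overrides optional function `(spec, class_label) -> spec`
#'   applied to each jittered spec before rendering
#' @return list of `labeled_image_pair` objects, length `4 * n_per_class`,
#'   grouped by class in the order sist, colon_cancer, adhesive, volvulus
#' @export
make_phantom_set <- function(n_per_class, seed = 0L, size = 256L,
                             noise_sd = 0.05, template_overrides = NULL) {
  check(is_count(n_per_class), "n_per_class must be >= 1")
  out <- vector("list", 4L * n_per_class)
  k <- 0L
  for (cls in PHANTOM_CLASSES) {
    for (i in seq_len(n_per_class)) {
      k <- k + 1L
      sk <- derive_seed(seed, k)
      spec <- with_seed(sk, jitter_spec(phantom_template(cls, size, noise_sd), size))
      if (!is.null(template_overrides)) spec <- template_overrides(spec, cls)
      out[[k]] <- make_phantom(spec, seed = derive_seed(seed, k + 100003L))
    }
  }
  out
}
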