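#' Cylinder surface area
#'
#' Lateral surface plus, optionally, the two end caps.  All spine sections
#' (PSD, head, neck) are modeled as cylinders; the published surfaces
#' include both caps.
#'
#' @param diameter cylinder diameter (um).
#' @param length cylinder length (um).
#' @param caps include the two circular end caps (default `TRUE`).
#' @return surface area (um^2).
#' @examples
#' cylinder_area(1.175, 1.0)   # spine head, 5.86 to 3 s.f.
#' @export
cylinder_area <- function(diameter, length, caps = TRUE) {
  stopifnot(diameter >= 0, length >= 0)
  a <- pi * diameter * length
  if (caps) a <- a + 2 * pi * (diameter / 2)^2
  a
}

#' Spine geometry
#'
#' Cylinder dimensions of the three electrical sections of a spine.
#' Defaults are the reference dimensions: PSD 0.5 x 0.05 um, head
#' 1.175 x 1.0 um, neck 0.1 x 1.5 um.
#'
#' @param psd,head,neck numeric `c(diameter, length)` in um.
#' @return list of class `"spine_geometry"` with per-section dimensions and
#'   surfaces.
#' @export
spine_geometry <- function(psd = c(0.5, 0.05),
                           head = c(1.175, 1.0),
                           neck = c(0.1, 1.5)) {
  sec <- list(psd = psd, head = head, neck = neck)
  for (s in sec) stopifnot(length(s) == 2, all(s >= 0))
  structure(list(
    psd = list(diameter = psd[1], length = psd[2],
               area = cylinder_area(psd[1], psd[2])),
    head = list(diameter = head[1], length = head[2],
                area = cylinder_area(head[1], head[2])),
    neck = list(diameter = neck[1], length = neck[2],
                area = cylinder_area(neck[1], neck[2]))
  ), class = "spine_geometry")
}

#' @export
print.spine_geometry <- function(x, ...) {
  cat("<spine_geometry> (um, um^2)\n")
  for (s in c("psd", "head", "neck")) {
    cat(sprintf("  %-4s d=%.3f L=%.3f area=%.3f\n",
                s, x[[s]]$diameter, x[[s]]$length, x[[s]]$area))
  }
  cat(sprintf("  exposed surface (head+neck): %.3f\n", spine_exposed_surface(x)))
  invisible(x)
}

#' Exposed membrane surface of one spine
#'
#' Head plus neck surface.  The PSD is an internal section of the head, so
#' its area is excluded from the exposed surface.  With the default
#' geometry this is 6.35 um^2 to 3 significant figures, the per-spine
#' equivalent area used by the budget and placement arithmetic.
#'
#' @param geom a [spine_geometry()].
#' @return exposed surface (um^2).
#' @export
spine_exposed_surface <- function(geom) {
  stopifnot(inherits(geom, "spine_geometry"))
  geom$head$area + geom$neck$area
}

#' Fold spine membrane into a dendrite (Segev correction)
#'
#' Rescales a dendritic cylinder so that its membrane absorbs the surface of
#' unmodeled spines: `length' = length * F^(2/3)` and
#' `diameter' = diameter * F^(1/3)`, where `F >= 1` is the ratio of
#' (dendrite + spine) area to dendrite area.  The lateral area then scales
#' exactly by `F` while axial-resistance consistency is preserved.
#'
#' @param length,diameter dendrite cylinder dimensions (um).
#' @param F area ratio, at least 1.
#' @return named numeric `c(length, diameter)` of the corrected cylinder.
#' @export
segev_fold <- function(length, diameter, F) {
  if (F < 1) stop("area ratio F must be >= 1")
  c(length = length * F^(2 / 3), diameter = diameter * F^(1 / 3))
}

#' Spine budget from corrected and original membrane surfaces
#'
#' Inverts the folding correction at the whole-cell level: the surface
#' deficit between the spine-corrected model and the bare-dendrite model,
#' divided by the per-spine equivalent area, gives the number of explicit
#' spines to instantiate.  The raw count is floored, then reduced to the
#' largest multiple of the number of primary dendrites so the tree stays
#' symmetric.  `proximal_noise` spines per branch are removed for spines
#' that the density data place over the soma and proximal dendrites (5 in
#' the reference dataset), yielding the final per-branch and total counts.
#'
#' @param corrected total membrane surface of the spine-corrected model
#'   (um^2).
#' @param original total membrane surface with original dimensions (um^2).
#' @param per_spine per-spine equivalent surface (um^2), e.g.
#'   [spine_exposed_surface()] of the default geometry.
#' @param n_dendrites number of primary dendrites (symmetry constraint).
#' @param proximal_noise spines per branch discarded as proximal noise
#'   (default 5).
#' @return list of class `"spine_budget"`.
#' @examples
#' spine_budget(14973, 5278, 6.35, 4)
#' @export
spine_budget <- function(corrected, original, per_spine, n_dendrites,
                         proximal_noise = 5L) {
  if (!(corrected > original)) stop("corrected surface must exceed original")
  if (!(per_spine > 0)) stop("per-spine surface must be positive")
  stopifnot(n_dendrites >= 1)
  deficit <- corrected - original
  raw <- floor(deficit / per_spine)
  symmetrized <- (raw %/% n_dendrites) * n_dendrites
  per_branch <- symmetrized / n_dendrites
  final_per_branch <- max(0L, per_branch - proximal_noise)
  structure(list(
    corrected = corrected, original = original, per_spine = per_spine,
    n_dendrites = n_dendrites, deficit = deficit,
    raw_count = as.integer(raw),
    symmetrized_count = as.integer(symmetrized),
    per_branch = as.integer(per_branch),
    final_per_branch = as.integer(final_per_branch),
    final_count = as.integer(final_per_branch * n_dendrites)
  ), class = "spine_budget")
}

#' @export
print.spine_budget <- function(x, ...) {
  cat("<spine_budget>\n")
  cat(sprintf("  surface deficit:    %g um^2 (%g - %g)\n",
              x$deficit, x$corrected, x$original))
  cat(sprintf("  raw spine count:    %d (deficit / %g um^2 per spine)\n",
              x$raw_count, x$per_spine))
  cat(sprintf("  symmetrized:        %d (%d per branch x %d dendrites)\n",
              x$symmetrized_count, x$per_branch, x$n_dendrites))
  cat(sprintf("  after noise removal: %d (%d per branch)\n",
              x$final_count, x$final_per_branch))
  invisible(x)
}

#' Fit a spine surface-density profile
#'
#' Least-squares polynomial fit of spine membrane surface per unit dendrite
#' length against distance from the soma, in the numerically stable
#' orthogonal basis (a raw power basis is ill-conditioned at order 17, the
#' default).  Fitted densities are clamped at zero when evaluated.
#'
#' @param points data frame with columns `distance_um` and `surface_per_um`.
#' @param order polynomial order (default 17).
#' @return object of class `"density_profile"`: the fit, residuals, and an
#'   evaluator.
#' @export
fit_density <- function(points, order = 17) {
  stopifnot(is.data.frame(points),
            all(c("distance_um", "surface_per_um") %in% names(points)))
  if (nrow(points) < order + 1) {
    stop(sprintf("need at least %d points for an order-%d fit", order + 1, order))
  }
  x <- points$distance_um
  y <- points$surface_per_um
  fit <- if (order == 0) {
    stats::lm(y ~ 1)
  } else {
    stats::lm(y ~ stats::poly(x, order))
  }
  structure(list(
    fit = fit,
    order = order,
    points = points,
    residuals = stats::residuals(fit),
    range = range(x)
  ), class = "density_profile")
}

#' Evaluate a fitted density profile
#'
#' @param profile a [fit_density()] result.
#' @param distance_um distances from the soma (um).
#' @param clamp clamp negative fitted densities to zero (default `TRUE`;
#'   clamping is counted and reported via `attr(, "n_clamped")`).
#' @return fitted surface density (um^2 per um).
#' @export
density_at <- function(profile, distance_um, clamp = TRUE) {
  stopifnot(inherits(profile, "density_profile"))
  pred <- if (profile$order == 0) {
    rep(stats::coef(profile$fit)[1], length(distance_um))
  } else {
    stats::predict(profile$fit, newdata = data.frame(x = distance_um))
  }
  pred <- as.numeric(pred)
  if (clamp) {
    n_neg <- sum(pred < 0)
    pred <- pmax(pred, 0)
    attr(pred, "n_clamped") <- n_neg
  }
  pred
}

#' @export
print.density_profile <- function(x, ...) {
  cat(sprintf("<density_profile> order-%d fit of %d points over [%g, %g] um\n",
              x$order, nrow(x$points), x$range[1], x$range[2]))
  cat(sprintf("  residual sd: %.4g\n", stats::sd(x$residuals)))
  invisible(x)
}

#' Synthetic spine surface-density profile
#'
#' Generates a sampled profile with the qualitative shape of measured spine
#' distributions on medium spiny neurons: essentially no spines over the
#' soma and proximal dendrites, a sharp rise to a peak around 50 um from
#' the soma, and a slow decay toward the distal tips.  The underlying curve
#' is a shifted gamma-like bump `A * u^k * exp(-u / theta)` with
#' `u = d - onset`; defaults put the peak at `onset + k * theta = 50` um.
#' Optional Gaussian sampling noise emulates digitization error (seeded,
#' deterministic).
#'
#' @param n_points number of samples (default 120).
#' @param max_dist outer sampling distance (um, default 220).
#' @param onset distance where spines begin (um, default 20).
#' @param k,theta shape parameters of the bump (defaults 2 and 15 um).
#' @param peak_density density at the peak (um^2/um, default 55).
#' @param noise_sd sd of additive sampling noise (um^2/um, default 0).
#' @param seed RNG seed used when `noise_sd > 0`.
#' @return data frame with `distance_um`, `surface_per_um`.
#' @export
synthetic_density_profile <- function(n_points = 120, max_dist = 220,
                                      onset = 20, k = 2, theta = 15,
                                      peak_density = 55, noise_sd = 0,
                                      seed = 1L) {
  d <- seq(0, max_dist, length.out = n_points)
  u <- pmax(d - onset, 0)
  bump <- u^k * exp(-u / theta)
  bump <- bump / max(bump) * peak_density
  if (noise_sd > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    bump <- pmax(bump + stats::rnorm(n_points, sd = noise_sd), 0)
  }
  data.frame(distance_um = d, surface_per_um = bump)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Place spines along a dendritic path from a density profile
#'
#' Integrates the fitted surface density along an ordered branch path,
#' divides by the per-dendrite share (a symmetric tree with `share`
#' primary dendrites splits the whole-cell profile evenly), and discretizes
#' the accumulated area by the per-spine equivalent surface: a spine is
#' emitted each time the running integral crosses a multiple of
#' `per_spine`.  Spines falling inside the proximal exclusion zone are
#' deleted.  The procedure is fully deterministic.
#'
#' @param profile a [fit_density()] result.
#' @param branch_path data frame with columns `segment` (name) and
#'   `length_um`, ordered from the soma outward; distances are cumulative.
#' @param per_spine per-spine equivalent surface (um^2, default 6.35).
#' @param exclusion proximal cutoff (um): spines closer to the soma are
#'   removed (default 0).
#' @param share number of primary dendrites sharing the whole-cell profile
#'   (default 4).
#' @param grid_um integration step (um, default 0.05).
#' @return data frame with `spine_id`, `segment`, `position_um` (within the
#'   segment) and `distance_um` (from the soma).
#' @export
distribute_spines <- function(profile, branch_path, per_spine = 6.35,
                              exclusion = 0, share = 4, grid_um = 0.05) {
  stopifnot(inherits(profile, "density_profile"),
            is.data.frame(branch_path),
            all(c("segment", "length_um") %in% names(branch_path)),
            exclusion >= 0, per_spine > 0, share >= 1)
  total_len <- sum(branch_path$length_um)
  d <- seq(0, total_len, by = grid_um)
  dens <- density_at(profile, d, clamp = TRUE)
  n_clamped <- attr(dens, "n_clamped") %||% 0L
  if (n_clamped > 0) {
    warning(sprintf("fitted density negative at %d of %d grid points; clamped to 0",
                    n_clamped, length(d)))
  }
  # trapezoid running integral of density / (share * per_spine)
  inc <- diff(d) * (utils::head(dens, -1) + utils::tail(dens, -1)) / 2
  cum <- cumsum(inc) / (share * per_spine)
  crossings <- findInterval(seq_len(floor(cum[length(cum)])), cum) + 1L
  pos <- d[pmin(crossings, length(d))]
  keep <- pos >= exclusion
  pos <- pos[keep]
  seg_end <- cumsum(branch_path$length_um)
  seg_idx <- findInterval(pos, seg_end, left.open = TRUE) + 1L
  seg_idx <- pmin(seg_idx, nrow(branch_path))
  seg_start <- c(0, utils::head(seg_end, -1))
  data.frame(
    spine_id = seq_along(pos),
    segment = branch_path$segment[seg_idx],
    position_um = pos - seg_start[seg_idx],
    distance_um = pos
  )
}
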